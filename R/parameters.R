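## Nearest-neighbor thermodynamic parameter sets.
##
## A parameter set holds every free-energy table the recursions need, the
## multibranch initiation constants a, b, c and the temperature.  Ordered
## canonical pairs are indexed in the fixed order AU UA GC CG GU UG; the
## "pair" dimension of every table runs over that order.  All energies are
## kcal/mol; the string "inf" in a parameter file encodes +Inf (a
## forbidden motif).

## 0 when not canonical, else 1..6 in CANONICAL_PAIRS order.
pair_index <- function(a, b) {
  match(paste0(a, b), CANONICAL_PAIRS, nomatch = 0L)
}

#' Are two bases a canonical pair?
#'
#' Canonical pairs are the Watson-Crick pairs A-U and G-C plus the G-U
#' wobble, in either orientation.
#'
#' @param x,y Single bases (characters among A, C, G, U).
#' @return `TRUE` iff `{x, y}` is one of AU, GC, GU (unordered).
#' @examples
#' canonical_pair("G", "C")  # TRUE
#' canonical_pair("G", "U")  # TRUE (wobble)
#' canonical_pair("A", "G")  # FALSE
#' @export
canonical_pair <- function(x, y) {
  stopifnot(x %in% RNA_BASES, y %in% RNA_BASES)
  pair_index(x, y) > 0L
}

## ---------------------------------------------------------------------
## Schema: section name -> expected shape.
param_schema <- function() {
  list(
    stack              = "pair_pair",
    hairpin_initiation = "size_3_30",
    hairpin_mismatch   = "pair_base_base",
    internal_initiation = "size_1_30",
    internal_mismatch  = "pair_base_base",
    dangle3            = "pair_base",
    dangle5            = "pair_base",
    multi_mismatch     = "pair_base_base",
    coax_flush         = "pair_pair",
    coax_mismatch1     = "pair_pair",
    coax_mismatch2     = "pair_pair",
    multibranch        = "abc",
    temperature        = "scalar"
  )
}

.num_or_inf <- function(x, where) {
  out <- vapply(x, function(v) {
    if (is.character(v)) {
      if (identical(tolower(v), "inf")) return(Inf)
      suppressWarnings(nv <- as.numeric(v))
      if (is.na(nv)) stop(sprintf("non-numeric entry '%s' in table '%s'", v, where),
                          call. = FALSE)
      return(nv)
    }
    if (!is.numeric(v) || is.na(v)) {
      stop(sprintf("non-numeric entry in table '%s'", where), call. = FALSE)
    }
    as.numeric(v)
  }, numeric(1))
  unname(out)
}

.parse_pair_pair <- function(sec, name) {
  m <- matrix(Inf, 6, 6, dimnames = list(CANONICAL_PAIRS, CANONICAL_PAIRS))
  missing <- setdiff(CANONICAL_PAIRS, names(sec))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing rows for pair(s) %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (p in CANONICAL_PAIRS) {
    row <- .num_or_inf(sec[[p]], name)
    if (length(row) != 6L) {
      stop(sprintf("table '%s', row %s: expected 6 values, got %d",
                   name, p, length(row)), call. = FALSE)
    }
    m[p, ] <- row
  }
  m
}

.parse_pair_base <- function(sec, name) {
  m <- matrix(Inf, 6, 4, dimnames = list(CANONICAL_PAIRS, RNA_BASES))
  missing <- setdiff(CANONICAL_PAIRS, names(sec))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing rows for pair(s) %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (p in CANONICAL_PAIRS) {
    row <- .num_or_inf(sec[[p]], name)
    if (length(row) != 4L) {
      stop(sprintf("table '%s', row %s: expected 4 values, got %d",
                   name, p, length(row)), call. = FALSE)
    }
    m[p, ] <- row
  }
  m
}

.parse_pair_base_base <- function(sec, name) {
  a <- array(Inf, c(6, 4, 4), dimnames = list(CANONICAL_PAIRS, RNA_BASES, RNA_BASES))
  missing <- setdiff(CANONICAL_PAIRS, names(sec))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing blocks for pair(s) %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (p in CANONICAL_PAIRS) {
    blk <- sec[[p]]
    missb <- setdiff(RNA_BASES, names(blk))
    if (length(missb)) {
      stop(sprintf("table '%s', block %s: missing base row(s) %s",
                   name, p, paste(missb, collapse = ", ")), call. = FALSE)
    }
    for (x in RNA_BASES) {
      row <- .num_or_inf(blk[[x]], name)
      if (length(row) != 4L) {
        stop(sprintf("table '%s', block %s/%s: expected 4 values",
                     name, p, x), call. = FALSE)
      }
      a[p, x, ] <- row
    }
  }
  a
}

.parse_sizes <- function(sec, name, from, to) {
  sizes <- as.character(from:to)
  missing <- setdiff(sizes, names(sec))
  if (length(missing)) {
    stop(sprintf("table '%s' is missing loop size(s) %s",
                 name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  vals <- .num_or_inf(sec[sizes], name)
  names(vals) <- sizes
  vals
}

#' Load, write and perturb nearest-neighbor parameter sets
#'
#' `load_parameters()` reads a structured-text (YAML) parameter file and
#' returns a validated `nn_parameters` object.  The packaged synthetic set
#' is available under the name `"toy-nn"`; it is complete and
#' thermodynamically plausible but deliberately not the published Turner
#' values.  `write_parameters()` serializes a set losslessly (full double
#' precision, `inf` for forbidden entries), so load -> save -> load is the
#' identity.
#'
#' The file contains exactly the sections `stack`, `hairpin_initiation`
#' (loop sizes 3..30), `hairpin_mismatch`, `internal_initiation` (total
#' unpaired 1..30), `internal_mismatch`, `dangle3`, `dangle5`,
#' `multi_mismatch`, `coax_flush`, `coax_mismatch1`, `coax_mismatch2`,
#' `multibranch` (constants `a`, `b`, `c` of the multibranch initiation
#' \eqn{\Delta G = a + b n + c h}) and `temperature` (kelvin).  Pair-indexed
#' tables have one row per ordered canonical pair (AU UA GC CG GU UG);
#' units are kcal/mol.  Loop initiations beyond tabulated size 30
#' extrapolate as \eqn{\Delta G(30) + 1.75 \, R T \log(n/30)}.
#'
#' @param source Path to a parameter file, or the packaged set name
#'   `"toy-nn"`.
#' @param gas_constant Gas constant in kcal/(mol K); the default is
#'   `GAS_CONSTANT_KCAL`.
#' @return An object of class `nn_parameters`: the parsed tables plus
#'   `multibranch` (named vector a, b, c), `temperature`, `gas_constant`.
#'   `RT` in kcal/mol is `gas_constant * temperature`.
#' @examples
#' p <- load_parameters("toy-nn")
#' p$multibranch
#' thermal_energy(p)
#' @export
load_parameters <- function(source, gas_constant = GAS_CONSTANT_KCAL) {
  path <- if (identical(source, "toy-nn")) {
    system.file("extdata", "toy_nn.yaml", package = "rnapf", mustWork = TRUE)
  } else {
    if (!file.exists(source)) stop(sprintf("parameter file '%s' not found", source),
                                   call. = FALSE)
    source
  }
  doc <- yaml::read_yaml(path)
  schema <- param_schema()
  missing <- setdiff(names(schema), names(doc))
  if (length(missing)) {
    stop(sprintf("parameter file is missing section(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  p <- list()
  p$stack               <- .parse_pair_pair(doc$stack, "stack")
  p$hairpin_initiation  <- .parse_sizes(doc$hairpin_initiation, "hairpin_initiation", 3, 30)
  p$hairpin_mismatch    <- .parse_pair_base_base(doc$hairpin_mismatch, "hairpin_mismatch")
  p$internal_initiation <- .parse_sizes(doc$internal_initiation, "internal_initiation", 1, 30)
  p$internal_mismatch   <- .parse_pair_base_base(doc$internal_mismatch, "internal_mismatch")
  p$dangle3             <- .parse_pair_base(doc$dangle3, "dangle3")
  p$dangle5             <- .parse_pair_base(doc$dangle5, "dangle5")
  p$multi_mismatch      <- .parse_pair_base_base(doc$multi_mismatch, "multi_mismatch")
  p$coax_flush          <- .parse_pair_pair(doc$coax_flush, "coax_flush")
  p$coax_mismatch1      <- .parse_pair_pair(doc$coax_mismatch1, "coax_mismatch1")
  p$coax_mismatch2      <- .parse_pair_pair(doc$coax_mismatch2, "coax_mismatch2")
  mb <- doc$multibranch
  for (k in c("a", "b", "c")) {
    if (is.null(mb[[k]])) stop("table 'multibranch' is missing constant ", k, call. = FALSE)
  }
  p$multibranch <- c(a = .num_or_inf(mb["a"], "multibranch"),
                     b = .num_or_inf(mb["b"], "multibranch"),
                     c = .num_or_inf(mb["c"], "multibranch"))
  names(p$multibranch) <- c("a", "b", "c")
  if (any(!is.finite(p$multibranch))) {
    stop("multibranch constants a, b, c must be finite", call. = FALSE)
  }
  p$temperature <- .num_or_inf(doc["temperature"], "temperature")
  if (!is.finite(p$temperature) || p$temperature <= 0) {
    stop("temperature must be a finite positive kelvin value", call. = FALSE)
  }
  p$gas_constant <- gas_constant
  structure(p, class = "nn_parameters")
}

#' RT product of a parameter set
#' @param params An `nn_parameters` object.
#' @return `gas_constant * temperature` in kcal/mol.
#' @rdname load_parameters
#' @export
thermal_energy <- function(params) {
  stopifnot(inherits(params, "nn_parameters"))
  params$gas_constant * params$temperature
}

#' @export
print.nn_parameters <- function(x, ...) {
  cat(sprintf(
    "nn_parameters: T = %.2f K, RT = %.4f kcal/mol\n  multibranch a = %.4g, b = %.4g, c = %.4g\n  tables: %s\n",
    x$temperature, thermal_energy(x),
    x$multibranch["a"], x$multibranch["b"], x$multibranch["c"],
    paste(setdiff(names(param_schema()), c("multibranch", "temperature")), collapse = ", ")
  ))
  invisible(x)
}

.fmt_g <- function(v) {
  vapply(v, function(x) {
    if (is.infinite(x)) "inf" else sprintf("%.17g", x)
  }, character(1))
}

.emit_pair_pair <- function(m) {
  paste0(vapply(CANONICAL_PAIRS, function(p) {
    sprintf("  %s: [%s]", p, paste(.fmt_g(m[p, ]), collapse = ", "))
  }, character(1)), collapse = "\n")
}

.emit_pair_base <- .emit_pair_pair  # same row layout, 4 columns

.emit_pair_base_base <- function(a) {
  paste0(vapply(CANONICAL_PAIRS, function(p) {
    rows <- vapply(RNA_BASES, function(x) {
      sprintf("    %s: [%s]", x, paste(.fmt_g(a[p, x, ]), collapse = ", "))
    }, character(1))
    paste0("  ", p, ":\n", paste(rows, collapse = "\n"))
  }, character(1)), collapse = "\n")
}

.emit_sizes <- function(v) {
  paste0(vapply(names(v), function(s) {
    sprintf("  \"%s\": %s", s, .fmt_g(v[[s]]))
  }, character(1)), collapse = "\n")
}

#' @param params Parameter set to write.
#' @param path Output file path.
#' @rdname load_parameters
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "nn_parameters"))
  txt <- c(
    "# nearest-neighbor parameter set (kcal/mol; 'inf' = forbidden motif)",
    sprintf("temperature: %s", .fmt_g(params$temperature)),
    "multibranch:",
    sprintf("  a: %s", .fmt_g(params$multibranch[["a"]])),
    sprintf("  b: %s", .fmt_g(params$multibranch[["b"]])),
    sprintf("  c: %s", .fmt_g(params$multibranch[["c"]])),
    "stack:", .emit_pair_pair(params$stack),
    "hairpin_initiation:", .emit_sizes(params$hairpin_initiation),
    "hairpin_mismatch:", .emit_pair_base_base(params$hairpin_mismatch),
    "internal_initiation:", .emit_sizes(params$internal_initiation),
    "internal_mismatch:", .emit_pair_base_base(params$internal_mismatch),
    "dangle3:", .emit_pair_base(params$dangle3),
    "dangle5:", .emit_pair_base(params$dangle5),
    "multi_mismatch:", .emit_pair_base_base(params$multi_mismatch),
    "coax_flush:", .emit_pair_pair(params$coax_flush),
    "coax_mismatch1:", .emit_pair_pair(params$coax_mismatch1),
    "coax_mismatch2:", .emit_pair_pair(params$coax_mismatch2)
  )
  writeLines(txt, path)
  invisible(path)
}

#' @details `perturb_parameters()` shifts every finite tabulated scalar
#' (all free-energy tables plus the multibranch constants a, b, c) by an
#' independent Gaussian(0, `sd`) draw from a seeded generator, mimicking
#' experimental parameter uncertainty.  `+Inf` entries (forbidden motifs)
#' and the temperature are untouched.  Draws are consumed in the fixed
#' schema order of the tables, column-major within each table, so a given
#' seed always produces the same perturbed set.
#'
#' @param sd Standard deviation of the Gaussian shift, kcal/mol.
#' @param seed Integer seed for the perturbation draws.
#' @rdname load_parameters
#' @export
perturb_parameters <- function(params, sd = 0.01, seed = 1L) {
  stopifnot(inherits(params, "nn_parameters"), sd >= 0)
  tables <- c(
    "stack", "hairpin_initiation", "hairpin_mismatch",
    "internal_initiation", "internal_mismatch", "dangle3", "dangle5",
    "multi_mismatch", "coax_flush", "coax_mismatch1", "coax_mismatch2",
    "multibranch"
  )
  out <- params
  withr::with_seed(seed, {
    for (tb in tables) {
      v <- out[[tb]]
      fin <- is.finite(v)
      v[fin] <- v[fin] + rnorm(sum(fin), mean = 0, sd = sd)
      out[[tb]] <- v
    }
  })
  out
}

## ---------------------------------------------------------------------
## Flat, RT-reduced table layout handed to the C++ fill.  Layout contract
## (0-based, row-major within a table) is mirrored in src/energy.h.
pack_tables <- function(params) {
  RTv <- thermal_energy(params)
  red <- function(x) x / RTv
  flat3 <- function(a) as.vector(aperm(a, c(3, 2, 1)))  # [p][x][y] -> p*16+x*4+y
  hp <- rep(Inf, 30)
  hp[3:30] <- params$hairpin_initiation[as.character(3:30)]
  il <- params$internal_initiation[as.character(1:30)]
  list(
    stack  = red(as.vector(t(params$stack))),
    hp_init = red(hp),
    hp_mm  = red(flat3(params$hairpin_mismatch)),
    il_init = red(as.numeric(il)),
    il_mm  = red(flat3(params$internal_mismatch)),
    d3     = red(as.vector(t(params$dangle3))),
    d5     = red(as.vector(t(params$dangle5))),
    tmm    = red(flat3(params$multi_mismatch)),
    cf     = red(as.vector(t(params$coax_flush))),
    cm1    = red(as.vector(t(params$coax_mismatch1))),
    cm2    = red(as.vector(t(params$coax_mismatch2))),
    abc    = red(as.numeric(params$multibranch)),
    RT     = RTv
  )
}
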