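# Synthetic nearest-neighbor parameter set for rnapf (kcal/mol).
# Complete and thermodynamically plausible; deliberately NOT the
# published Turner values.  'inf' would mark a forbidden entry.
temperature: 310.15
multibranch:
  a: 3.40
  b: 0.40
  c: 0.90
stack:
  AU: [-1.48, -1.50, -1.88, -2.06, -1.36, -1.40]
  UA: [-1.54, -1.48, -2.02, -1.84, -1.06, -1.24]
  GC: [-1.84, -2.06, -2.45, -2.47, -1.80, -1.77]
  CG: [-2.02, -1.88, -2.36, -2.45, -1.95, -1.72]
  GU: [-1.24, -1.40, -1.72, -1.77, -1.04, -0.89]
  UG: [-1.06, -1.36, -1.95, -1.80, -1.04, -1.04]
hairpin_initiation:
  "3": 5.40
  "4": 5.86
  "5": 6.22
  "6": 6.51
  "7": 6.76
  "8": 6.97
  "9": 7.16
  "10": 7.33
  "11": 7.48
  "12": 7.62
  "13": 7.75
  "14": 7.86
  "15": 7.98
  "16": 8.08
  "17": 8.18
  "18": 8.27
  "19": 8.35
  "20": 8.44
  "21": 8.51
  "22": 8.59
  "23": 8.66
  "24": 8.73
  "25": 8.79
  "26": 8.86
  "27": 8.92
  "28": 8.97
  "29": 9.03
  "30": 9.08
hairpin_mismatch:
  AU:
    A: [-0.49, -0.99, -0.35, -0.27]
    C: [-0.32, -0.51, -0.83, -1.42]
    G: [-0.74, -0.60, -0.81, -1.45]
    U: [-0.99, -0.43, -0.53, -0.44]
  UA:
    A: [-0.47, -0.48, -1.35, -0.60]
    C: [-1.10, -0.86, -0.95, -0.79]
    G: [-1.01, -1.31, -0.91, -0.94]
    U: [-0.96, -1.00, -1.21, -1.45]
  GC:
    A: [-1.37, -0.85, -0.33, -0.74]
    C: [-0.79, -0.47, -1.49, -0.78]
    G: [-0.77, -1.07, -0.72, -0.98]
    U: [-0.76, -1.47, -1.28, -1.01]
  CG:
    A: [-1.02, -1.11, -1.19, -0.50]
    C: [-1.14, -1.05, -1.43, -0.87]
    G: [-0.43, -0.85, -0.93, -0.96]
    U: [-0.89, -0.78, -0.56, -0.71]
  GU:
    A: [-1.44, -1.22, -0.31, -0.40]
    C: [-0.26, -1.10, -0.51, -0.83]
    G: [-0.45, -1.18, -1.18, -1.25]
    U: [-0.71, -0.44, -0.77, -0.91]
  UG:
    A: [-1.32, -1.38, -1.18, -0.43]
    C: [-0.56, -0.54, -0.53, -0.26]
    G: [-1.23, -0.49, -0.81, -0.82]
    U: [-0.70, -0.31, -1.17, -1.03]
internal_initiation:
  "1": 3.20
  "2": 3.96
  "3": 4.41
  "4": 4.72
  "5": 4.97
  "6": 5.17
  "7": 5.34
  "8": 5.49
  "9": 5.62
  "10": 5.73
  "11": 5.84
  "12": 5.93
  "13": 6.02
  "14": 6.10
  "15": 6.18
  "16": 6.25
  "17": 6.32
  "18": 6.38
  "19": 6.44
  "20": 6.50
  "21": 6.55
  "22": 6.60
  "23": 6.65
  "24": 6.70
  "25": 6.74
  "26": 6.78
  "27": 6.83
  "28": 6.87
  "29": 6.90
  "30": 6.94
internal_mismatch:
  AU:
    A: [-0.89, -0.94, -0.34, -0.81]
    C: [-0.19, -0.30, -0.44, -1.10]
    G: [-0.19, -0.42, -0.57, -0.85]
    U: [-0.92, -1.11, -0.57, -0.17]
  UA:
    A: [-0.98, -0.79, -0.44, -0.96]
    C: [-0.45, -0.99, -0.97, -0.42]
    G: [-0.78, -1.05, -0.80, -0.21]
    U: [-0.76, -0.22, -0.30, -0.79]
  GC:
    A: [-0.70, -0.77, -0.79, -0.36]
    C: [-0.44, -0.64, -0.44, -1.02]
    G: [-0.53, -0.46, -0.51, -0.35]
    U: [-0.81, -0.12, -1.04, -0.44]
  CG:
    A: [-0.70, -0.57, -0.57, -0.96]
    C: [-0.12, -0.19, -0.19, -0.85]
    G: [-0.14, -0.53, -0.25, -0.86]
    U: [-0.94, -0.60, -1.12, -0.66]
  GU:
    A: [-0.61, -0.20, -0.77, -0.65]
    C: [-1.14, -1.10, -0.86, -0.91]
    G: [-1.11, -0.39, -0.16, -0.27]
    U: [-0.58, -0.67, -0.43, -0.17]
  UG:
    A: [-1.06, -0.28, -1.06, -0.69]
    C: [-0.72, -1.00, -0.62, -0.98]
    G: [-0.72, -0.36, -0.23, -0.52]
    U: [-0.92, -0.86, -1.09, -0.41]
dangle3:
  AU: [-0.42, -0.26, -0.76, -0.37]
  UA: [-0.16, -0.70, -0.73, -0.30]
  GC: [-0.69, -0.12, -0.19, -0.64]
  CG: [-0.16, -0.38, -0.17, -0.59]
  GU: [-0.48, -0.14, -0.16, -0.77]
  UG: [-0.38, -0.21, -0.15, -0.65]
dangle5:
  AU: [-0.39, -0.47, -0.14, -0.45]
  UA: [-0.27, -0.23, -0.60, -0.07]
  GC: [-0.34, -0.42, -0.25, -0.50]
  CG: [-0.23, -0.56, -0.42, -0.48]
  GU: [-0.36, -0.44, -0.23, -0.53]
  UG: [-0.36, -0.25, -0.29, -0.43]
multi_mismatch:
  AU:
    A: [-1.25, -1.31, -0.45, -1.35]
    C: [-0.67, -1.12, -0.41, -1.27]
    G: [-0.32, -0.87, -0.46, -1.09]
    U: [-0.80, -1.01, -0.70, -0.52]
  UA:
    A: [-1.40, -1.21, -0.91, -0.67]
    C: [-0.36, -1.02, -0.40, -0.45]
    G: [-0.39, -0.56, -1.13, -0.97]
    U: [-0.49, -0.83, -0.85, -0.47]
  GC:
    A: [-0.84, -0.62, -0.39, -0.51]
    C: [-0.79, -0.40, -1.36, -1.40]
    G: [-0.83, -0.57, -0.77, -0.75]
    U: [-0.41, -1.13, -0.85, -1.06]
  CG:
    A: [-0.74, -0.78, -0.36, -0.69]
    C: [-1.40, -0.34, -0.52, -0.39]
    G: [-0.38, -1.32, -0.62, -0.87]
    U: [-0.74, -1.16, -1.30, -1.34]
  GU:
    A: [-0.46, -0.52, -0.83, -1.36]
    C: [-0.55, -0.50, -0.99, -0.55]
    G: [-0.40, -0.33, -1.10, -0.43]
    U: [-0.52, -0.45, -0.87, -0.86]
  UG:
    A: [-1.21, -0.81, -0.68, -1.03]
    C: [-0.31, -1.17, -0.88, -1.14]
    G: [-0.88, -0.86, -0.82, -1.28]
    U: [-1.03, -0.79, -0.67, -1.32]
coax_flush:
  AU: [-2.08, -2.24, -2.40, -2.48, -1.93, -2.12]
  UA: [-1.97, -2.11, -2.52, -2.38, -1.91, -2.12]
  GC: [-2.48, -2.53, -2.90, -3.00, -2.22, -2.32]
  CG: [-2.40, -2.52, -2.91, -2.92, -2.54, -2.21]
  GU: [-1.95, -2.02, -2.42, -2.29, -1.72, -1.97]
  UG: [-2.19, -1.90, -2.39, -2.57, -1.84, -2.04]
coax_mismatch1:
  AU: [-1.82, -1.76, -1.91, -2.00, -1.68, -1.65]
  UA: [-1.84, -1.71, -2.21, -1.83, -1.50, -1.64]
  GC: [-2.00, -2.03, -2.47, -2.41, -1.95, -1.83]
  CG: [-1.97, -1.86, -2.50, -2.33, -1.89, -2.04]
  GU: [-1.51, -1.33, -1.70, -1.83, -1.20, -1.30]
  UG: [-1.71, -1.65, -1.68, -1.85, -1.33, -1.24]
coax_mismatch2:
  AU: [-1.69, -1.84, -1.84, -1.89, -1.65, -1.38]
  UA: [-1.85, -1.69, -1.90, -1.98, -1.70, -1.52]
  GC: [-2.16, -1.99, -2.33, -2.42, -1.96, -1.90]
  CG: [-1.84, -2.20, -2.42, -2.52, -1.95, -1.98]
  GU: [-1.63, -1.40, -1.85, -1.88, -1.44, -1.31]
  UG: [-1.68, -1.72, -1.70, -1.70, -1.58, -1.45]
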