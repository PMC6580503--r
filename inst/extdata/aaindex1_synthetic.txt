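H SYNKAC401
D Unfolding activation free energy proxy, pH 7.0 (synthetic values; stand-in
  scale shipped for examples and tests, not a published AAindex entry)
R
A
T
J
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     8.1     9.8     7.4     7.2    10.5     8.0     7.6     6.3     9.1    11.8
    11.2     8.6    10.1    12.3     5.9     6.8     7.9    12.9    11.0    10.7
//
H SYNKAC402
D Unfolding activation free energy proxy, pH 9.0 (synthetic values; stand-in
  scale shipped for examples and tests, not a published AAindex entry)
R
A
T
J
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     7.6     9.2     7.0     6.5    10.9     7.7     6.9     6.0     8.8    12.1
    11.5     8.0     9.8    12.6     5.5     6.4     7.5    13.2    10.6    11.0
//
H SYNKAC403
D Normalized backbone flexibility (B-value) proxy, one rigid neighbour
  (synthetic values; stand-in scale, not a published AAindex entry)
R
A
T
J
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.98    1.04    1.07    1.09    0.91    1.05    1.08    1.12    0.99    0.93
    0.95    1.10    0.96    0.92    1.13    1.08    1.03    0.90    0.94    0.94
//
H SYNKAC404
D Averaged turn propensity in a transmembrane helix (synthetic values;
  stand-in scale, not a published AAindex entry)
R
A
T
J
C
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    0.37    0.52    0.61    0.58    0.41    0.49    0.50    0.70    0.55    0.26
    0.29    0.56    0.33    0.31    0.88    0.60    0.48    0.44    0.46    0.27
//
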