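H SYNX001
D synthetic example property 1 (randomly generated; not from the AAindex database)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -1.913    0.269   -0.437    0.291   -0.934    0.168    0.303    0.264    0.186   -0.093
    -1.366   -1.129    0.536   -0.162    -0.35    0.881   -1.387    -0.97   -0.569    1.736
//
H SYNX002
D synthetic example property 2 (randomly generated; not from the AAindex database)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.15   -0.312   -2.297    0.424   -0.102   -0.659     0.92    0.429   -1.396   -0.048
     1.213   -0.513     0.29   -0.765   -0.119    0.171    0.681    0.142   -1.235    0.217
//
H SYNX003
D synthetic example property 3 (randomly generated; not from the AAindex database)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.561   -0.358    0.599    0.868    0.418     0.56     0.95    -0.61    1.208   -0.534
     0.278    0.861   -0.623   -0.588    1.859   -0.833   -1.073   -0.432   -0.497    1.513
//
H SYNX004
D synthetic example property 4 (randomly generated; not from the AAindex database)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.905    0.466    1.104     0.22   -0.324   -1.097    0.724   -0.845      0.4    1.539
     2.056    0.767    0.015   -0.115    0.004    0.615    0.651    1.164   -0.382   -0.444
//
H SYNX005
D synthetic example property 5 (randomly generated; not from the AAindex database)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -2.947    0.769   -0.309   -1.298   -1.618    0.294   -1.012    0.132   -1.249    0.554
    -0.242    0.265   -0.491    0.927    -0.37   -0.789   -0.456   -0.099   -0.876   -1.779
//
H SYNX006
D synthetic example property 6 (randomly generated; not from the AAindex database)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
        NA    0.103    0.487    0.756    0.417   -1.592   -0.837    -0.89   -2.322   -1.014
    -0.695   -1.244    1.544    1.426   -1.247   -0.217    1.352    1.656   -0.005   -0.009
//
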