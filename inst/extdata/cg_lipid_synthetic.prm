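* CG lipid force field parameters
* cutoff 12.0 A, exclude-1-2
*

BONDS
CHO    PO2        6.0000     3.6000
PO2    COH        7.5000     3.3000
COH    MTF        8.0000     3.1000
MTF    C3M        6.5000     3.0500
C3M    C3M        5.5000     3.0000
C3M    C2M        5.8000     2.7000
C3M    D3M        5.2000     3.0000
C3M    C3E        5.5000     3.0500
C2M    C2E        6.0000     2.5000
C3M    C2E        5.8000     2.7500

ANGLES
CHO    PO2    COH        3.0000   112.0000
PO2    COH    MTF        3.2000    95.0000
MTF    COH    MTF        2.8000   110.0000
COH    MTF    C3M        3.0000   130.0000
MTF    C3M    C3M        2.4000   150.0000
C3M    C3M    C3M        2.2000   155.0000
C2M    C3M    C3M        2.2000   152.0000
C3M    C3M    D3M        2.0000   150.0000
C2M    C3M    D3M        2.0000   150.0000
C3M    D3M    C3M        1.6000   120.0000
C3E    C3M    C3M        2.2000   155.0000
C2E    C3M    C3M        2.2000   152.0000
C2E    C2M    C3M        2.3000   150.0000

NONBONDED
CHO           0.0  -0.800000     2.8342
PO2           0.0  -1.000000     2.4694
COH           0.0  -0.750000     2.7781
MTF           0.0  -0.700000     2.6378
C3M           0.0  -0.550000     2.5985
C2M           0.0  -0.450000     2.3010
D3M           0.0  -0.600000     2.6378
C3E           0.0  -0.550000     2.5985
C2E           0.0  -0.450000     2.3010
W             0.0  -0.850000     2.2169

NBFIX
CHO    W       -0.900000     5.1072
PO2    W       -1.000000     4.8266
COH    W       -0.800000     5.0511
MTF    W       -0.600000     4.9388

END
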