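metric_a,location_a,metric_b,location_b,r
MAI,chest,MAI,ankle,0.91
MAI,hip,MAI,ankle,0.95
MAI,hip,MAI,chest,0.98
MAI,thigh,MAI,ankle,0.97
MAI,thigh,MAI,chest,0.95
MAI,thigh,MAI,hip,0.98
MAI,upper_arm,MAI,ankle,0.83
MAI,upper_arm,MAI,chest,0.94
MAI,upper_arm,MAI,hip,0.92
MAI,upper_arm,MAI,thigh,0.89
MAI,wrist,MAI,ankle,0.71
MAI,wrist,MAI,chest,0.86
MAI,wrist,MAI,hip,0.82
MAI,wrist,MAI,thigh,0.78
MAI,wrist,MAI,upper_arm,0.95
ENMO,ankle,MAI,ankle,0.97
ENMO,ankle,MAI,chest,0.92
ENMO,ankle,MAI,hip,0.94
ENMO,ankle,MAI,thigh,0.96
ENMO,ankle,MAI,upper_arm,0.84
ENMO,ankle,MAI,wrist,0.73
ENMO,chest,MAI,ankle,0.89
ENMO,chest,MAI,chest,0.97
ENMO,chest,MAI,hip,0.95
ENMO,chest,MAI,thigh,0.93
ENMO,chest,MAI,upper_arm,0.91
ENMO,chest,MAI,wrist,0.83
ENMO,chest,ENMO,ankle,0.92
ENMO,hip,MAI,ankle,0.91
ENMO,hip,MAI,chest,0.95
ENMO,hip,MAI,hip,0.98
ENMO,hip,MAI,thigh,0.95
ENMO,hip,MAI,upper_arm,0.9
ENMO,hip,MAI,wrist,0.81
ENMO,hip,ENMO,ankle,0.94
ENMO,hip,ENMO,chest,0.97
ENMO,thigh,MAI,ankle,0.92
ENMO,thigh,MAI,chest,0.93
ENMO,thigh,MAI,hip,0.95
ENMO,thigh,MAI,thigh,0.97
ENMO,thigh,MAI,upper_arm,0.88
ENMO,thigh,MAI,wrist,0.78
ENMO,thigh,ENMO,ankle,0.96
ENMO,thigh,ENMO,chest,0.95
ENMO,thigh,ENMO,hip,0.96
ENMO,upper_arm,MAI,ankle,0.8
ENMO,upper_arm,MAI,chest,0.9
ENMO,upper_arm,MAI,hip,0.88
ENMO,upper_arm,MAI,thigh,0.86
ENMO,upper_arm,MAI,upper_arm,0.96
ENMO,upper_arm,MAI,wrist,0.86
ENMO,upper_arm,ENMO,ankle,0.84
ENMO,upper_arm,ENMO,chest,0.9
ENMO,upper_arm,ENMO,hip,0.89
ENMO,upper_arm,ENMO,thigh,0.88
ENMO,wrist,MAI,ankle,0.75
ENMO,wrist,MAI,chest,0.87
ENMO,wrist,MAI,hip,0.84
ENMO,wrist,MAI,thigh,0.81
ENMO,wrist,MAI,upper_arm,0.92
ENMO,wrist,MAI,wrist,0.94
ENMO,wrist,ENMO,ankle,0.78
ENMO,wrist,ENMO,chest,0.87
ENMO,wrist,ENMO,hip,0.85
ENMO,wrist,ENMO,thigh,0.83
ENMO,wrist,ENMO,upper_arm,0.89
MAD,ankle,MAI,ankle,0.97
MAD,ankle,MAI,chest,0.89
MAD,ankle,MAI,hip,0.93
MAD,ankle,MAI,thigh,0.95
MAD,ankle,MAI,upper_arm,0.8
MAD,ankle,MAI,wrist,0.68
MAD,ankle,ENMO,ankle,0.95
MAD,ankle,ENMO,chest,0.88
MAD,ankle,ENMO,hip,0.9
MAD,ankle,ENMO,thigh,0.91
MAD,ankle,ENMO,upper_arm,0.78
MAD,ankle,ENMO,wrist,0.73
MAD,chest,MAI,ankle,0.91
MAD,chest,MAI,chest,0.97
MAD,chest,MAI,hip,0.97
MAD,chest,MAI,thigh,0.95
MAD,chest,MAI,upper_arm,0.91
MAD,chest,MAI,wrist,0.83
MAD,chest,ENMO,ankle,0.93
MAD,chest,ENMO,chest,0.98
MAD,chest,ENMO,hip,0.97
MAD,chest,ENMO,thigh,0.95
MAD,chest,ENMO,upper_arm,0.9
MAD,chest,ENMO,wrist,0.86
MAD,chest,MAD,ankle,0.91
MAD,hip,MAI,ankle,0.93
MAD,hip,MAI,chest,0.96
MAD,hip,MAI,hip,0.98
MAD,hip,MAI,thigh,0.96
MAD,hip,MAI,upper_arm,0.9
MAD,hip,MAI,wrist,0.8
MAD,hip,ENMO,ankle,0.94
MAD,hip,ENMO,chest,0.97
MAD,hip,ENMO,hip,0.98
MAD,hip,ENMO,thigh,0.95
MAD,hip,ENMO,upper_arm,0.88
MAD,hip,ENMO,wrist,0.84
MAD,hip,MAD,ankle,0.93
MAD,hip,MAD,chest,0.99
MAD,thigh,MAI,ankle,0.95
MAD,thigh,MAI,chest,0.93
MAD,thigh,MAI,hip,0.95
MAD,thigh,MAI,thigh,0.97
MAD,thigh,MAI,upper_arm,0.85
MAD,thigh,MAI,wrist,0.75
MAD,thigh,ENMO,ankle,0.96
MAD,thigh,ENMO,chest,0.93
MAD,thigh,ENMO,hip,0.95
MAD,thigh,ENMO,thigh,0.96
MAD,thigh,ENMO,upper_arm,0.84
MAD,thigh,ENMO,wrist,0.8
MAD,thigh,MAD,ankle,0.96
MAD,thigh,MAD,chest,0.94
MAD,thigh,MAD,hip,0.96
MAD,upper_arm,MAI,ankle,0.85
MAD,upper_arm,MAI,chest,0.93
MAD,upper_arm,MAI,hip,0.92
MAD,upper_arm,MAI,thigh,0.9
MAD,upper_arm,MAI,upper_arm,0.96
MAD,upper_arm,MAI,wrist,0.87
MAD,upper_arm,ENMO,ankle,0.86
MAD,upper_arm,ENMO,chest,0.92
MAD,upper_arm,ENMO,hip,0.91
MAD,upper_arm,ENMO,thigh,0.89
MAD,upper_arm,ENMO,upper_arm,0.94
MAD,upper_arm,ENMO,wrist,0.87
MAD,upper_arm,MAD,ankle,0.85
MAD,upper_arm,MAD,chest,0.94
MAD,upper_arm,MAD,hip,0.92
MAD,upper_arm,MAD,thigh,0.88
MAD,wrist,MAI,ankle,0.76
MAD,wrist,MAI,chest,0.89
MAD,wrist,MAI,hip,0.86
MAD,wrist,MAI,thigh,0.83
MAD,wrist,MAI,upper_arm,0.94
MAD,wrist,MAI,wrist,0.95
MAD,wrist,ENMO,ankle,0.78
MAD,wrist,ENMO,chest,0.87
MAD,wrist,ENMO,hip,0.85
MAD,wrist,ENMO,thigh,0.83
MAD,wrist,ENMO,upper_arm,0.88
MAD,wrist,ENMO,wrist,0.93
MAD,wrist,MAD,ankle,0.74
MAD,wrist,MAD,chest,0.88
MAD,wrist,MAD,hip,0.85
MAD,wrist,MAD,thigh,0.8
MAD,wrist,MAD,upper_arm,0.93
CPM,ankle,MAI,ankle,0.98
CPM,ankle,MAI,chest,0.91
CPM,ankle,MAI,hip,0.94
CPM,ankle,MAI,thigh,0.96
CPM,ankle,MAI,upper_arm,0.84
CPM,ankle,MAI,wrist,0.72
CPM,ankle,ENMO,ankle,0.95
CPM,ankle,ENMO,chest,0.91
CPM,ankle,ENMO,hip,0.92
CPM,ankle,ENMO,thigh,0.92
CPM,ankle,ENMO,upper_arm,0.82
CPM,ankle,ENMO,wrist,0.77
CPM,ankle,MAD,ankle,0.95
CPM,ankle,MAD,chest,0.92
CPM,ankle,MAD,hip,0.93
CPM,ankle,MAD,thigh,0.95
CPM,ankle,MAD,upper_arm,0.87
CPM,ankle,MAD,wrist,0.77
CPM,chest,MAI,ankle,0.78
CPM,chest,MAI,chest,0.9
CPM,chest,MAI,hip,0.86
CPM,chest,MAI,thigh,0.82
CPM,chest,MAI,upper_arm,0.83
CPM,chest,MAI,wrist,0.76
CPM,chest,ENMO,ankle,0.76
CPM,chest,ENMO,chest,0.81
CPM,chest,ENMO,hip,0.8
CPM,chest,ENMO,thigh,0.78
CPM,chest,ENMO,upper_arm,0.75
CPM,chest,ENMO,wrist,0.74
CPM,chest,MAD,ankle,0.76
CPM,chest,MAD,chest,0.83
CPM,chest,MAD,hip,0.82
CPM,chest,MAD,thigh,0.79
CPM,chest,MAD,upper_arm,0.8
CPM,chest,MAD,wrist,0.77
CPM,chest,CPM,ankle,0.77
CPM,hip,MAI,ankle,0.86
CPM,hip,MAI,chest,0.9
CPM,hip,MAI,hip,0.92
CPM,hip,MAI,thigh,0.89
CPM,hip,MAI,upper_arm,0.82
CPM,hip,MAI,wrist,0.73
CPM,hip,ENMO,ankle,0.83
CPM,hip,ENMO,chest,0.85
CPM,hip,ENMO,hip,0.86
CPM,hip,ENMO,thigh,0.83
CPM,hip,ENMO,upper_arm,0.76
CPM,hip,ENMO,wrist,0.73
CPM,hip,MAD,ankle,0.84
CPM,hip,MAD,chest,0.87
CPM,hip,MAD,hip,0.88
CPM,hip,MAD,thigh,0.86
CPM,hip,MAD,upper_arm,0.82
CPM,hip,MAD,wrist,0.76
CPM,hip,CPM,ankle,0.85
CPM,hip,CPM,chest,0.92
CPM,thigh,MAI,ankle,0.92
CPM,thigh,MAI,chest,0.89
CPM,thigh,MAI,hip,0.91
CPM,thigh,MAI,thigh,0.94
CPM,thigh,MAI,upper_arm,0.83
CPM,thigh,MAI,wrist,0.73
CPM,thigh,ENMO,ankle,0.88
CPM,thigh,ENMO,chest,0.86
CPM,thigh,ENMO,hip,0.87
CPM,thigh,ENMO,thigh,0.88
CPM,thigh,ENMO,upper_arm,0.8
CPM,thigh,ENMO,wrist,0.75
CPM,thigh,MAD,ankle,0.89
CPM,thigh,MAD,chest,0.87
CPM,thigh,MAD,hip,0.88
CPM,thigh,MAD,thigh,0.9
CPM,thigh,MAD,upper_arm,0.84
CPM,thigh,MAD,wrist,0.77
CPM,thigh,CPM,ankle,0.94
CPM,thigh,CPM,chest,0.81
CPM,thigh,CPM,hip,0.88
CPM,upper_arm,MAI,ankle,0.74
CPM,upper_arm,MAI,chest,0.86
CPM,upper_arm,MAI,hip,0.82
CPM,upper_arm,MAI,thigh,0.8
CPM,upper_arm,MAI,upper_arm,0.95
CPM,upper_arm,MAI,wrist,0.88
CPM,upper_arm,ENMO,ankle,0.74
CPM,upper_arm,ENMO,chest,0.81
CPM,upper_arm,ENMO,hip,0.8
CPM,upper_arm,ENMO,thigh,0.78
CPM,upper_arm,ENMO,upper_arm,0.89
CPM,upper_arm,ENMO,wrist,0.82
CPM,upper_arm,MAD,ankle,0.7
CPM,upper_arm,MAD,chest,0.81
CPM,upper_arm,MAD,hip,0.8
CPM,upper_arm,MAD,thigh,0.76
CPM,upper_arm,MAD,upper_arm,0.88
CPM,upper_arm,MAD,wrist,0.85
CPM,upper_arm,CPM,ankle,0.75
CPM,upper_arm,CPM,chest,0.81
CPM,upper_arm,CPM,hip,0.77
CPM,upper_arm,CPM,thigh,0.77
CPM,wrist,MAI,ankle,0.59
CPM,wrist,MAI,chest,0.74
CPM,wrist,MAI,hip,0.69
CPM,wrist,MAI,thigh,0.65
CPM,wrist,MAI,upper_arm,0.85
CPM,wrist,MAI,wrist,0.94
CPM,wrist,ENMO,ankle,0.6
CPM,wrist,ENMO,chest,0.68
CPM,wrist,ENMO,hip,0.67
CPM,wrist,ENMO,thigh,0.64
CPM,wrist,ENMO,upper_arm,0.72
CPM,wrist,ENMO,wrist,0.84
CPM,wrist,MAD,ankle,0.55
CPM,wrist,MAD,chest,0.68
CPM,wrist,MAD,hip,0.66
CPM,wrist,MAD,thigh,0.61
CPM,wrist,MAD,upper_arm,0.74
CPM,wrist,MAD,wrist,0.84
CPM,wrist,CPM,ankle,0.59
CPM,wrist,CPM,chest,0.7
CPM,wrist,CPM,hip,0.65
CPM,wrist,CPM,thigh,0.62
CPM,wrist,CPM,upper_arm,0.84
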