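"date","value"
"1996-01-01",7.83
"1996-01-02",8.25
"1996-01-03",8.76
"1996-01-04",8.02
"1996-01-05",8.4
"1996-01-06",8.51
"1996-01-07",8.71
"1996-01-08",8.43
"1996-01-09",9.08
"1996-01-10",8.41
"1996-01-11",8.53
"1996-01-12",8.63
"1996-01-13",8.14
"1996-01-14",7.86
"1996-01-15",8.61
"1996-01-16",7.28
"1996-01-17",8.14
"1996-01-18",7.79
"1996-01-19",8
"1996-01-20",7.75
"1996-01-21",8.19
"1996-01-22",7.16
"1996-01-23",7.98
"1996-01-24",8.09
"1996-01-25",7.52
"1996-01-26",6.82
"1996-01-27",7.76
"1996-01-28",7.51
"1996-01-29",8.01
"1996-01-30",7.95
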