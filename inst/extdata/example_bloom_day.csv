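"year","value"
1996,101
1997,98
1998,104
1999,93
2000,89
2001,90
2002,81
2003,88
2004,91
2005,93
2006,92
2007,79
2008,88
2009,110
2010,100
2011,111
2012,93
2013,94
2014,94
2015,85
2016,88
2017,112
2018,91
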