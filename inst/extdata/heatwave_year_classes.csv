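year,class
2006,Before
2007,Before
2008,Before
2009,Before
2010,Before
2011,Before
2012,Before
2013,Before
2014,Heatwave
2015,Heatwave
2016,Heatwave
2017,Between
2018,Between
2019,Heatwave
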