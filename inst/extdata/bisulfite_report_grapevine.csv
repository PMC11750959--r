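sample,total_analyzed,meth_cg,meth_chg,meth_chh,meth_unknown
G+_1,259133083,284782,263603,920187,1032
G+_2,546752409,608384,558261,1918117,2126
G+_3,314771657,355313,325031,1210998,1103
G-_1,159367452,199134,180869,617520,587
G-_2,168998804,179576,159608,500726,673
G-_3,162348402,208515,190078,597758,632
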