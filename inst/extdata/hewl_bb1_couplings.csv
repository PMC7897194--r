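residue,resid,J_exp,J_exp_capped,MD_2VB1,X_2VB1,MD_4LZT,X_4LZT,MD_1IEE,X_1IEE,MD_1AKI,X_1AKI,MD_mean,X_mean,MD_rmsd,X_rmsd
Val,2,10.0,9.7,7.9,9.6,7.8,9.4,8.3,8.7,7.3,9.1,7.8,9.2,0.4,0.3
Phe,3,7.4,,7.5,6.1,7.0,5.7,6.4,5.2,7.4,6.1,7.1,5.8,0.4,0.4
Cys,6,5.8,,5.5,5.8,5.7,5.7,6.3,5.0,5.5,5.5,5.8,5.5,0.3,0.3
Glu,7,4.5,,4.3,4.6,4.2,4.8,4.1,3.6,4.3,4.9,4.2,4.5,0.1,0.5
Leu,8,5.5,,4.7,5.1,4.7,4.9,4.6,5.0,4.6,4.5,4.7,4.9,0.1,0.2
Ala,9,3.7,,4.2,3.7,4.2,3.8,4.2,3.6,4.2,2.8,4.2,3.5,0.0,0.4
Ala,10,3.9,,4.5,4.8,4.5,4.8,4.6,4.3,4.5,4.9,4.5,4.7,0.0,0.2
Ala,11,4.8,,4.5,4.7,4.6,4.9,4.5,5.3,4.7,4.4,4.6,4.8,0.1,0.3
Met,12,4.6,,4.9,4.5,4.5,5.0,4.6,4.3,4.6,4.4,4.7,4.6,0.2,0.3
Lys,13,4.2,,4.7,4.8,4.4,4.8,4.6,4.7,4.7,4.4,4.6,4.7,0.1,0.2
Arg,14,4.4,,4.6,4.1,4.8,4.4,4.7,4.4,4.5,4.6,4.7,4.4,0.1,0.2
His,15,9.2,,7.4,7.6,7.4,8.3,7.6,7.3,7.4,8.1,7.5,7.8,0.1,0.4
Leu,17,7.6,,7.0,7.5,7.4,6.8,7.4,7.4,7.4,6.6,7.3,7.1,0.2,0.4
Asp,18,5.7,,6.0,5.3,7.0,5.1,6.8,4.5,6.2,4.2,6.5,4.8,0.4,0.5
Asn,19,7.0,,6.4,6.6,5.7,6.7,6.3,6.9,6.7,6.6,6.3,6.7,0.4,0.1
Tyr,20,5.5,,7.0,5.0,6.5,5.3,6.7,4.7,5.0,4.7,6.3,4.9,0.8,0.3
Arg,21,6.8,,6.0,6.7,6.3,6.8,5.6,6.7,6.6,6.9,6.1,6.8,0.4,0.1
Tyr,23,8.6,,7.8,9.5,7.1,9.2,8.2,8.8,7.3,9.6,7.6,9.3,0.4,0.3
Asn,27,5.4,,4.2,4.0,4.5,4.1,4.1,4.0,4.3,3.7,4.3,4.0,0.1,0.2
Trp,28,6.0,,5.2,5.2,5.0,5.4,5.2,5.4,5.1,4.6,5.1,5.2,0.1,0.3
Val,29,5.9,,4.8,4.9,4.8,4.8,4.8,4.8,4.9,4.2,4.8,4.7,0.0,0.3
Cys,30,3.8,,4.6,4.0,4.4,4.3,4.6,4.0,4.9,3.6,4.6,4.0,0.2,0.2
Ala,31,3.8,,4.4,4.2,4.2,4.2,4.3,4.2,4.6,4.1,4.4,4.2,0.1,0.0
Ala,32,4.8,,4.5,4.7,4.3,4.7,4.6,4.5,4.8,3.5,4.6,4.4,0.2,0.5
Lys,33,3.6,,4.6,3.6,5.2,3.9,4.6,3.8,5.7,4.1,5.0,3.9,0.5,0.2
Phe,34,7.6,,5.6,7.7,5.2,7.6,6.1,7.5,5.3,7.4,5.6,7.6,0.4,0.1
Glu,35,7.2,,7.7,5.6,6.9,6.2,7.8,6.6,7.1,6.2,7.4,6.2,0.4,0.4
Ser,36,9.6,,7.9,9.4,8.5,9.4,7.6,9.4,5.7,9.7,7.4,9.5,1.0,0.1
Phe,38,6.3,,6.8,6.8,6.8,6.8,6.8,6.8,6.8,6.8,6.8,6.8,0.0,0.0
Asn,39,8.8,,8.1,8.6,7.9,8.9,7.2,8.8,7.6,9.5,7.7,9.0,0.3,0.3
Thr,40,5.4,,4.7,4.7,4.7,4.8,4.7,4.3,4.5,4.6,4.7,4.6,0.1,0.2
Gln,41,9.2,,6.5,8.7,6.7,8.6,6.7,7.7,6.9,9.1,6.7,8.5,0.1,0.5
Ala,42,4.5,,5.6,4.0,6.0,4.4,5.6,4.5,5.6,4.4,5.7,4.3,0.2,0.2
Thr,43,9.3,,8.7,9.2,8.8,9.0,8.9,9.2,8.8,9.2,8.8,9.1,0.1,0.1
Asn,44,9.4,,7.7,9.2,8.1,9.5,7.8,8.3,7.7,8.8,7.8,8.9,0.2,0.5
Arg,45,7.7,,8.1,8.4,7.8,8.2,7.7,6.3,7.6,8.2,7.8,7.8,0.2,0.9
Asn,46,8.8,,6.1,7.5,7.9,7.9,8.1,8.1,7.3,9.6,7.4,8.3,0.8,0.8
Thr,47,4.4,,4.2,6.2,4.3,6.1,4.3,4.1,4.4,4.3,4.3,5.2,0.1,1.0
Asp,48,7.7,,6.3,6.8,5.7,7.3,5.7,6.5,6.1,6.2,6.0,6.7,0.3,0.4
Ser,50,7.8,,5.3,8.0,5.8,8.3,5.9,6.2,5.7,6.5,5.7,7.3,0.2,0.9
Thr,51,9.8,9.7,8.3,9.0,9.2,9.2,9.2,9.3,8.9,9.6,8.9,9.3,0.4,0.2
Asp,52,9.6,,8.0,9.0,7.6,9.0,7.4,9.1,7.6,8.4,7.7,8.9,0.2,0.3
Tyr,53,9.6,,8.9,9.7,8.5,9.7,8.7,9.5,8.1,9.7,8.6,9.7,0.3,0.1
Leu,56,9.7,,7.3,9.5,8.3,9.5,7.7,9.7,8.0,9.4,7.8,9.5,0.4,0.1
Gln,57,6.3,,6.8,6.7,6.6,6.7,6.8,6.7,6.7,6.4,6.7,6.6,0.1,0.1
Ile,58,8.0,,8.0,7.2,8.1,7.1,7.9,8.1,7.9,7.4,8.0,7.4,0.1,0.4
Ser,60,5.1,,5.2,7.1,5.0,6.9,5.1,8.3,4.9,5.9,5.1,7.1,0.0,0.9
Arg,61,6.2,,5.7,6.7,5.6,6.2,5.9,7.8,6.2,5.3,5.9,6.5,0.2,0.9
Cys,64,8.8,,7.5,9.4,8.4,9.2,7.6,9.3,9.1,9.4,8.2,9.3,0.7,0.1
Asn,65,9.4,,6.3,8.8,6.5,8.9,6.0,9.0,5.9,9.0,6.2,8.9,0.2,0.1
Asp,66,10.0,9.7,8.1,9.6,8.5,9.6,8.3,9.7,8.4,9.6,8.3,9.6,0.1,0.0
Arg,68,9.7,,6.9,9.6,6.8,9.7,6.7,9.2,6.7,9.4,6.8,9.5,0.1,0.2
Thr,69,9.3,,6.0,9.5,5.8,8.9,5.6,9.6,6.3,9.6,5.9,9.4,0.3,0.3
Cys,76,8.8,,7.4,7.2,7.8,7.1,7.1,6.8,7.1,7.9,7.4,7.3,0.3,0.4
Asn,77,7.4,,6.8,6.9,6.8,6.9,6.8,6.6,6.7,6.9,6.8,6.8,0.0,0.1
Ile,78,8.0,,4.7,8.3,4.6,8.2,5.1,6.7,5.8,8.9,5.1,8.0,0.5,0.8
Cys,80,3.6,,4.5,4.5,4.5,4.4,4.5,4.0,4.4,4.1,4.5,4.2,0.0,0.2
Ser,81,3.6,,4.0,4.1,3.9,4.2,3.9,4.3,3.9,3.3,3.9,4.0,0.0,0.4
Ala,82,5.4,,4.7,4.7,4.7,4.6,4.8,4.7,4.8,5.1,4.8,4.8,0.1,0.2
Leu,83,7.2,,5.3,6.4,5.1,6.9,5.3,7.2,5.2,6.6,5.2,6.8,0.1,0.3
Leu,84,9.2,,5.6,9.4,6.2,9.4,5.9,9.2,6.0,8.9,5.9,9.2,0.2,0.2
Ser,85,5.8,,6.3,5.2,5.7,6.0,6.6,4.2,5.9,5.0,6.1,5.1,0.3,0.6
Ser,86,5.8,,4.9,5.8,4.6,5.9,4.8,4.3,4.9,5.7,4.8,5.4,0.1,0.7
Asp,87,8.9,,6.5,6.4,7.9,7.0,6.8,7.2,7.5,7.2,7.2,7.0,0.6,0.3
Ile,88,6.5,,7.3,8.0,6.8,7.8,6.6,7.1,7.4,7.0,7.0,7.5,0.3,0.5
Ala,90,4.2,,4.5,5.2,4.8,4.9,4.5,4.9,4.5,3.3,4.6,4.6,0.1,0.7
Ser,91,5.5,,4.2,4.7,4.3,4.6,4.5,4.4,4.3,4.4,4.3,4.5,0.1,0.1
Val,92,5.6,,4.8,4.8,4.5,5.0,5.0,4.8,4.8,4.2,4.8,4.7,0.2,0.3
Asn,93,4.4,,4.5,4.7,4.4,4.4,4.5,4.1,4.6,4.0,4.5,4.3,0.1,0.3
Cys,94,6.3,,5.1,5.5,5.6,5.7,5.2,5.6,5.2,5.1,5.3,5.5,0.2,0.2
Lys,96,4.4,,4.3,4.3,4.1,4.6,4.4,4.3,4.2,4.2,4.3,4.4,0.1,0.2
Lys,97,6.5,,4.7,4.5,5.4,4.8,5.1,4.6,4.9,5.5,5.0,4.9,0.3,0.4
Val,99,5.2,,5.9,6.1,5.4,5.2,5.0,5.8,6.6,6.1,5.7,5.8,0.6,0.3
Asp,101,7.0,,6.1,7.9,7.3,7.3,6.4,6.3,6.6,5.8,6.6,6.8,0.4,0.8
Asn,103,8.2,,5.4,6.6,5.6,8.9,6.4,9.4,6.8,9.2,6.1,8.5,0.6,1.1
Met,105,7.4,,7.0,3.8,4.6,5.4,6.5,6.2,6.4,7.4,6.1,5.7,0.9,1.3
Ala,107,4.2,,5.2,4.2,5.8,4.2,5.6,3.6,6.0,4.5,5.7,4.1,0.3,0.3
Trp,108,9.6,,5.9,8.7,6.2,8.9,6.0,8.1,5.7,9.1,6.0,8.7,0.2,0.4
Val,109,4.0,,4.7,3.8,4.4,4.1,5.1,5.3,4.6,4.3,4.7,4.4,0.3,0.6
Trp,111,7.1,,5.4,4.8,5.4,4.6,5.0,4.8,5.0,4.6,5.2,4.7,0.2,0.1
Arg,112,4.5,,4.1,4.3,4.5,4.5,6.4,4.2,4.4,3.3,4.9,4.1,0.9,0.5
Asn,113,5.8,,7.3,7.2,8.2,8.1,6.1,6.7,6.3,5.6,7.0,6.9,0.8,0.9
Arg,114,9.6,,7.3,9.6,5.0,9.6,8.0,9.6,7.3,9.7,6.9,9.6,1.1,0.1
Cys,115,9.8,9.7,6.2,9.6,7.7,9.7,8.4,9.6,6.4,9.3,7.2,9.5,0.9,0.2
Thr,118,9.8,9.7,6.8,9.5,7.1,8.8,6.7,7.9,6.9,8.9,6.9,8.8,0.1,0.6
Asp,119,6.7,,5.9,6.5,5.5,6.9,6.1,6.6,6.3,6.3,6.0,6.6,0.3,0.2
Val,120,4.6,,6.4,5.0,4.9,6.1,6.7,5.3,5.8,5.0,6.0,5.4,0.7,0.5
Gln,121,5.0,,4.2,4.0,5.4,5.0,4.5,4.4,4.9,4.1,4.8,4.4,0.5,0.4
Ala,122,3.7,,4.9,3.5,4.3,3.5,4.6,3.6,4.6,2.8,4.6,3.4,0.2,0.3
Trp,123,5.4,,6.0,5.8,5.5,6.2,6.3,5.4,6.4,4.9,6.1,5.6,0.4,0.5
Ile,124,10.6,9.7,6.7,9.6,6.7,9.7,7.0,9.4,7.1,9.5,6.9,9.6,0.2,0.1
Arg,125,4.4,,5.9,4.7,6.2,4.7,5.5,4.0,6.4,5.2,6.0,4.7,0.3,0.4
Cys,127,7.7,,5.6,7.6,6.0,7.5,6.4,6.4,7.1,8.9,6.3,7.6,0.6,0.9
Arg,128,8.0,,6.8,6.0,6.8,6.7,7.4,8.5,7.4,7.8,7.1,7.3,0.3,1.0
Leu,129,9.0,,7.5,9.6,7.5,9.2,7.5,9.4,7.3,9.3,7.5,9.4,0.1,0.1
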