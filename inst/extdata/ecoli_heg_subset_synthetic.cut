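# Synthetic codon usage table in EMBOSS .cut format (bacterial code 11).
# Only the GCA and GCG counts reproduce the EMBOSS-distributed E. coli
# highly-expressed-gene table; every other row is a synthetic placeholder
# for parser testing. Columns: Codon AA Fraction /1000 Number.

TTT F 0.484 21.68 828
CTT L 0.245 22.18 847
ATT I 0.366 7.67 293
GTT V 0.317 19.79 756
TCT S 0.200 15.58 595
CCT P 0.306 12.86 491
ACT T 0.274 17.70 676
GCT A 0.029 4.29 164
TAT Y 0.835 15.92 608
CAT H 0.571 16.99 649
AAT N 0.535 11.49 439
GAT D 0.446 17.31 661
TGT C 0.662 22.10 844
CGT R 0.062 6.99 267
AGT S 0.149 11.60 443
GGT G 0.313 22.23 849
TTC F 0.516 23.07 881
CTC L 0.043 3.93 150
ATC I 0.568 11.89 454
GTC V 0.221 13.77 526
TCC S 0.275 21.42 818
CCC P 0.105 4.40 168
ACC T 0.361 23.33 891
GCC A 0.151 22.39 855
TAC Y 0.165 3.14 120
CAC H 0.429 12.75 487
AAC N 0.465 10.00 382
GAC D 0.554 21.47 820
TGC C 0.338 11.26 430
CGC R 0.178 19.93 761
AGC S 0.227 17.73 677
GGC G 0.272 19.35 739
TTA L 0.110 9.95 380
CTA L 0.183 16.55 632
ATA I 0.066 1.39 53
GTA V 0.318 19.85 758
TCA S 0.019 1.47 56
CCA P 0.142 5.94 227
ACA T 0.332 21.50 821
GCA A 0.349 51.66 1973
TAA * 0.263 9.77 373
CAA Q 0.682 11.00 420
AAA K 0.232 2.15 82
GAA E 0.643 22.99 878
TGA * 0.294 10.92 417
CGA R 0.202 22.62 864
AGA R 0.188 21.08 805
GGA G 0.219 15.55 594
TTG L 0.253 22.91 875
CTG L 0.166 15.08 576
ATG M 1.000 8.72 333
GTG V 0.145 9.03 345
TCG S 0.131 10.19 389
CCG P 0.447 18.77 717
ACG T 0.034 2.17 83
GCG A 0.470 69.49 2654
TAG * 0.442 16.39 626
CAG Q 0.318 5.13 196
AAG K 0.768 7.12 272
GAG E 0.357 12.75 487
TGG W 1.000 16.34 624
CGG R 0.207 23.17 885
AGG R 0.163 18.22 696
GGG G 0.196 13.93 532
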