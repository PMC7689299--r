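# Mouse pore-forming (alpha subunit) ion channel gene universe, 270 symbols.
# Curated synthetic stand-in snapshot assembled from the standard channel
# gene families (voltage-gated K/Na/Ca, TRP, intracellular release, CNG/HCN,
# chloride, ligand-gated, and other pore-forming subunits); matches the size
# and composition style of the IUPHAR mouse list but is not a download of it.
Kcna1
Kcna2
Kcna3
Kcna4
Kcna5
Kcna6
Kcna7
Kcna10
Kcnb1
Kcnb2
Kcnc1
Kcnc2
Kcnc3
Kcnc4
Kcnd1
Kcnd2
Kcnd3
Kcnf1
Kcng1
Kcng2
Kcng3
Kcng4
Kcnh1
Kcnh2
Kcnh3
Kcnh4
Kcnh5
Kcnh6
Kcnh7
Kcnh8
Kcnq1
Kcnq2
Kcnq3
Kcnq4
Kcnq5
Kcns1
Kcns2
Kcns3
Kcnv1
Kcnv2
Kcnma1
Kcnn1
Kcnn2
Kcnn3
Kcnn4
Kcnt1
Kcnt2
Kcnu1
Kcnj1
Kcnj2
Kcnj3
Kcnj4
Kcnj5
Kcnj6
Kcnj8
Kcnj9
Kcnj10
Kcnj11
Kcnj12
Kcnj13
Kcnj14
Kcnj15
Kcnj16
Kcnk1
Kcnk2
Kcnk3
Kcnk4
Kcnk5
Kcnk6
Kcnk7
Kcnk9
Kcnk10
Kcnk12
Kcnk13
Kcnk15
Kcnk16
Kcnk18
Hcn1
Hcn2
Hcn3
Hcn4
Cacna1a
Cacna1b
Cacna1c
Cacna1d
Cacna1e
Cacna1f
Cacna1g
Cacna1h
Cacna1i
Cacna1s
Scn1a
Scn2a
Scn3a
Scn4a
Scn5a
Scn7a
Scn8a
Scn9a
Scn10a
Scn11a
Nalcn
Trpa1
Trpc1
Trpc2
Trpc3
Trpc4
Trpc5
Trpc6
Trpc7
Trpm1
Trpm2
Trpm3
Trpm4
Trpm5
Trpm6
Trpm7
Trpm8
Trpv1
Trpv2
Trpv3
Trpv4
Trpv5
Trpv6
Mcoln1
Mcoln2
Mcoln3
Pkd2
Pkd2l1
Pkd2l2
Ryr1
Ryr2
Ryr3
Itpr1
Itpr2
Itpr3
Tpcn1
Tpcn2
Catsper1
Catsper2
Catsper3
Catsper4
Cnga1
Cnga2
Cnga3
Cnga4
Cngb1
Cngb3
Asic1
Asic2
Asic3
Asic4
Asic5
Scnn1a
Scnn1b
Scnn1g
Clcn1
Clcn2
Clcn3
Clcn4
Clcn5
Clcn6
Clcn7
Clcnka
Clcnkb
Ano1
Ano2
Ano3
Ano4
Ano5
Ano6
Ano7
Ano8
Ano9
Ano10
Best1
Best2
Best3
Cftr
Hvcn1
Chrna1
Chrna2
Chrna3
Chrna4
Chrna5
Chrna6
Chrna7
Chrna9
Chrna10
Chrnb1
Chrnb2
Chrnb3
Chrnb4
Chrnd
Chrne
Chrng
Gabra1
Gabra2
Gabra3
Gabra4
Gabra5
Gabra6
Gabrb1
Gabrb2
Gabrb3
Gabrg1
Gabrg2
Gabrg3
Gabrd
Gabre
Gabrp
Gabrq
Gabrr1
Gabrr2
Gabrr3
Glra1
Glra2
Glra3
Glra4
Glrb
Gria1
Gria2
Gria3
Gria4
Grik1
Grik2
Grik3
Grik4
Grik5
Grin1
Grin2a
Grin2b
Grin2c
Grin2d
Grin3a
Grin3b
Grid1
Grid2
Htr3a
Htr3b
P2rx1
P2rx2
P2rx3
P2rx4
P2rx5
P2rx6
P2rx7
Zacn
Orai1
Orai2
Orai3
Piezo1
Piezo2
Tmc1
Tmc2
Lrrc8a
Tmem63a
Tmem63b
Tmem63c
Pkd1l3
Gja1
Gja3
Gja4
Gja5
Tmem38a
Tmem38b
Clic1
Clic4
Clic5
Clic6
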