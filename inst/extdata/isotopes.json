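{"H":[[1.00782503207,0.999885],[2.01410177785,0.000115]],"D":[[2.01410177785,1]],"C":[[12,0.9893],[13.00335483521,0.0107]],"N":[[14.00307400425,0.99636],[15.00010889827,0.00364]],"O":[[15.99491461926,0.99757],[16.99913175595,0.00038],[17.99915961214,0.00205]],"F":[[18.99840316207,1]],"Na":[[22.98976928195,1]],"Si":[[27.97692653442,0.92223],[28.97649466434,0.04685],[29.973770137,0.03092]],"P":[[30.97376199768,1]],"S":[[31.97207117354,0.9499],[32.97145890862,0.0075],[33.967867011,0.0425],[35.9670807,0.0001]],"Cl":[[34.968852694,0.7576],[36.965902584,0.2424]],"K":[[38.9637064848,0.932581],[39.963998165,0.000117],[40.9618252561,0.067302]],"Br":[[78.9183376,0.5069],[80.9162897,0.4931]],"I":[[126.9044719,1]]}
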