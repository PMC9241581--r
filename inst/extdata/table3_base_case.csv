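country,arm,cost,qaly,ly,icer_vs_ref_printed,seq_icer_printed,label_printed
UK,Gefitinib,24529,1.130,2.571,-1217,NA,on_frontier
UK,Osimertinib,139483,1.762,3.485,112412,1269085,on_frontier
UK,Afatinib,51865,1.255,2.899,52570,NA,dominated
UK,Dacomitinib,155510,1.475,3.080,178439,NA,dominated
UK,Erlotinib,27237,1.177,2.554,5169,NA,extended_dominated
UK,Afatinib+Cetuximab,92935,1.113,2.535,184107,NA,dominated
UK,Erlotinib+Bevacizumab,106486,1.541,2.950,102246,NA,dominated
UK,Gefitinib+Pemetrexed,33221,1.401,3.080,12513,32144,on_frontier
UK,Gefitinib+PbCT,44445,1.687,3.632,20609,39175,on_frontier
UK,PbCT,31595,0.861,2.426,56160,NA,dominated
UK,PfCT,24999,0.744,2.607,NA,NA,dominated
China,Gefitinib,12961,1.312,2.572,-7266,NA,on_frontier
China,Osimertinib,25459,1.935,3.485,12215,224999,on_frontier
China,Afatinib,21478,1.469,2.900,16418,NA,dominated
China,Icotinib,18308,1.254,2.482,18310,NA,dominated
China,Dacomitinib,22517,1.656,3.081,13009,NA,dominated
China,Erlotinib,19270,1.340,2.554,16118,NA,dominated
China,Afatinib+Cetuximab,52380,1.297,2.536,159297,NA,dominated
China,Erlotinib+Bevacizumab,58504,1.673,2.951,71527,NA,dominated
China,Gefitinib+Pemetrexed,16873,1.606,3.081,3842,13289,on_frontier
China,Gefitinib+PbCT,21545,1.918,3.633,7895,14966,on_frontier
China,PbCT,16066,1.101,2.427,32121,NA,dominated
China,PfCT,14780,1.061,2.607,NA,NA,dominated
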