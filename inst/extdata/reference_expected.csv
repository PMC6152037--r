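"name","smiles","dHvap","dHsub","dHsolv","dSfus","tpcE"
"n-butane","CCCC",24.45,44.65,-26.09,51.84,78.88
"n-hexane","CCCCCC",33.97,57.35,-31.89,68.76,86.96
"isobutane","CC(C)C",21.72,39.16,-25.32,37.46,66.29
"neopentane","CC(C)(C)C",23.26,38.09,-25.86,38.49,80.93
"cyclohexane","C1CCCCC1",37.17,59.13,-30.73,55.36,77.54
"cyclopropane","C1CC1",22.89,40.08,-22.03,44.86,NA
"cyclobutane","C1CCC1",27.65,46.43,-24.93,56.76,NA
"cyclopentane","C1CCCC1",32.41,52.78,-27.83,51.92,111.49
"benzene","c1ccccc1",36.03,52.59,-28.87,46.54,80.36
"toluene","Cc1ccccc1",39.68,56.24,-31.94,43.29,72.74
"styrene","C=Cc1ccccc1",43.74,63.22,-32.34,49.34,79.25
"naphthalene","c1ccc2ccccc2c1",58.37,73.93,-40.01,48.48,70.3
"ethanol","CCO",42.02,61.13,-50.26,45.54,86.32
"2-propanol","CC(C)O",44.29,61.77,-54.39,43.55,71.7
"diethyl ether","CCOCC",28.47,53.02,-44.13,59.29,72.5
"acetone","CC(C)=O",28.34,48.11,-39.86,36.49,73.6
"acetic acid","CC(O)=O",49.86,69.27,-53.3,42.09,90
"methyl acetate","COC(C)=O",32.3,58.26,-39.42,47.4,76.08
"phenol","Oc1ccccc1",60.83,76.48,-55.45,50.18,89.21
"anisole","COc1ccccc1",43.27,65.47,-41.57,55.49,75.29
"aniline","Nc1ccccc1",54.3,76.42,-54.01,51.48,-3.33
"triethylamine","CCN(CC)CC",32.32,53.87,-63.01,49.33,-4.09
"pyridine","c1ccncc1",40.91,59.5,-46.11,46.6,88.8
"pyrimidine","c1cncnc1",41.89,58.04,NA,45.77,NA
"furan","c1ccoc1",32.02,40.95,NA,30.92,80.51
"thiophene","c1ccsc1",35.6,53.73,NA,28.22,NA
"pyrrole","c1cc[nH]c1",50.6,76.71,-42.12,34.47,49.67
"nitromethane","C[N+](=O)[O-]",NA,NA,NA,NA,NA
"nitrobenzene","O=[N+]([O-])c1ccccc1",54.1,72.12,-40.51,49.68,72.08
"acetonitrile","CC#N",29.06,43.51,-35.43,35.68,70.19
"1-iodopropane","CCCI",37.25,NA,NA,NA,NA
"bromoethane","CCBr",28.37,49.78,NA,44.81,55.23
"2,2,2-trifluoroethanol","OCC(F)(F)F",41.91,50.43,-48.67,47.02,72.69
"ethylene glycol","OCCO",56.84,80.62,NA,62.47,84
"salicylaldehyde","O=Cc1ccccc1O",60.47,86.35,NA,59.63,73.74
"dimethyl sulfide","CSC",26.98,58.46,-32.29,46.88,NA
"dimethyl sulfoxide","CS(C)=O",60.09,NA,NA,46.52,NA
"trimethyl phosphate","COP(=O)(OC)OC",46.75,NA,NA,NA,NA
"tetramethylsilane","C[Si](C)(C)C",31.52,NA,NA,51.83,NA
"triethylborane","CCB(CC)CC",NA,NA,NA,NA,NA
"furazan","O1N=CC=N1",46.05,65.4,NA,NA,NA
"N-methylacetamide","CC(=O)NC",60.74,80.13,-76.66,39.47,98.38
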