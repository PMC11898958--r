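id,name,chi_c18,chi_iam,logk_hsa,pct_hsa
1,Azinphos-ethyl,95.69,37.81,1.01,92.07
2,Azinphos-methyl,83.47,33.18,0.78,86.70
3,Chlorfenvinphos,97.18,38.13,0.74,85.54
4,Chlorpyrifos-oxon,39.17,24.96,0.68,83.49
5,Diazinon,105.98,39.34,0.62,81.33
6,Dichlorvos,23.17,16.56,0.27,65.86
7,Disulfoton,108.97,42.34,1.06,92.86
8,Ethoprophos,88.39,32.41,-0.41,28.35
9,Fenitrothion,93.49,38.10,1.00,91.78
10,Fenthion,102.16,42.37,1.29,96.04
11,Mecarbam,97.09,35.77,0.44,74.23
12,Naled,31.32,29.79,-0.11,43.86
13,Paraoxon-ethyl,72.54,25.34,-0.42,27.68
14,Parathion-methyl,88.75,35.54,0.83,87.94
15,Phorate,108.36,42.43,1.07,93.08
16,Phosmet,85.39,33.89,0.80,87.23
17,Quinalphos,101.01,39.40,0.97,91.23
18,Triazophos,92.96,38.08,0.74,85.43
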