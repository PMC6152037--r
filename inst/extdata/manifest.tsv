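file	md5
params_dHvap.tsv	516c1d8da9197ea071ff4f7b16bcb1c7
params_dHsub.tsv	2fda860712cbe62648d88f57d70adae0
params_dHsolv.tsv	2e024d99df435785c9adb14052305b31
params_dSfus.tsv	b6201b52211f97bc75199c51b288d13f
params_tpcE.tsv	24ca9368ce022b2cf6b668ca8359923b
reported_stats.tsv	006ac596818c7115e73dd0d98b35ef11
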