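file,md5
table1_gloves.csv,70dbd0acad3faf5601f03e13e32242f3
table3_transmissibilities.csv,fc27daf02908c063b92aaf3840bb0bbd
table4_reductions.csv,1a5d3618fc1827e324a6c1f9d4c1d3a7
table5_transmissibilities.csv,cf1acf4a2e460faf7551f4e5783e9dbe
tool_accel_summaries.csv,d5486d3acd3aa84d088000078cb7f38c
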