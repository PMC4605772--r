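# Evolved klinotaxis circuit (synthetic): genetic-algorithm product of this
# package (evolution_config(pop_size = 48, generations = 400), seed 102,
# conical gradient field). Chemotaxis index 0.837.
w_ON_AIYL 1320.9582719103696
w_ON_AIYR -931.14318294380769
w_OFF_AIYL -1500
w_OFF_AIYR -976.99614613595543
w_AIYL_AIZL 15
w_AIYR_AIZR 15
w_AIZL_SMBDL 15
w_AIZL_SMBVL 15
w_AIZR_SMBDR -15
w_AIZR_SMBVR -15
w_SMBDL_SMBDL 0.85604333362532081
w_SMBDR_SMBDR -15
w_SMBVL_SMBVL 0.85604333362532081
w_SMBVR_SMBVR -15
g_AIY 2.5
g_AIZ 2.5
theta_AIYL -2.2681932925186263
theta_AIYR 6.2511408609020123
theta_AIZL -5.7769336537156128
theta_AIZR -15
theta_SMBDL -3.7052462895185769
theta_SMBDR -5.9905440155075009
theta_SMBVL -3.7052462895185769
theta_SMBVR -5.9905440155075009
w_PG -9.9800613164111684
w_NMJ -2
tau 0.10000000000000001
T 4.2000000000000002
v 0.021999999999999999
N 1
M 210
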