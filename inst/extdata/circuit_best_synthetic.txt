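# Evolved klinotaxis circuit (synthetic): genetic-algorithm product of this
# package (evolution_config(pop_size = 48, generations = 400), seed 109,
# conical gradient field); highest-fitness circuit exhibiting the
# ensemble-typical information architecture. Chemotaxis index 0.834.
w_ON_AIYL 787.96798903892932
w_ON_AIYR 1403.3835050296111
w_OFF_AIYL -1500
w_OFF_AIYR -1061.5098819251045
w_AIYL_AIZL 8.5272599593281626
w_AIYR_AIZR 14.646344894847058
w_AIZL_SMBDL -15
w_AIZL_SMBVL -15
w_AIZR_SMBDR -15
w_AIZR_SMBVR -15
w_SMBDL_SMBDL -7.8573618300500057
w_SMBDR_SMBDR -0.9642860144129326
w_SMBVL_SMBVL -7.8573618300500057
w_SMBVR_SMBVR -0.9642860144129326
g_AIY 1.9473231746704265
g_AIZ 2.0152622066066703
theta_AIYL -0.4698289558635409
theta_AIYR -9.3218212422519287
theta_AIZL -2.7472762790588181
theta_AIZR -2.8291286296798646
theta_SMBDL -4.7230975771091437
theta_SMBDR -1.5185679130038352
theta_SMBVL -4.7230975771091437
theta_SMBVR -1.5185679130038352
w_PG 15
w_NMJ 1.6485970366189902
tau 0.10000000000000001
T 4.2000000000000002
v 0.021999999999999999
N 1
M 149
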