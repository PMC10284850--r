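# Desk-scale study conditions (reduced geometry; see the methods vignette).
profile = "desk"
tau = 0.005
tau_save = 0.5
T = 60
L = 18
epsilon = 0.15
v0 = 1.0
a = 1.5
Ca = 0.2
In = 0.1
D_r = 0.1
alpha = 0.1
N = 13
grid_n = 256
seed = 1
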