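# Reference parameter set for the persistent-activity network experiment.
# Any key omitted here falls back to the package default (which is this
# same setting); values shown explicitly for documentation.

# single neuron
E_L = -70
E_E = 10
E_I = -80
C_S = 740
C_D = 50
g_S = 30
g_D = 20
g_SI = 5
g_SE = 10
g_IE = 1
alpha = 5

# network
N_E = 2000
N_I = 500
p = 0.1
w_E = 24
w_I = 2
C_S_E = 740
C_S_I = 370
tau_E = 100
tau_I = 10
E_thres = -50
E_reset = -70
stim_onset = 50
stim_offset = 250
dt = 0.1
seed = 1

# calibrated once (spontaneous rate <= 2 Hz, reliable switching), frozen
sigma = 2
g_ext = 10

# mean-field (published linearization constants)
mu_E = 3.2
mu_I = 6.4
beta = 17.5
a = 0.002
b = 0.175
c = -0.113
d = -0.6218
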