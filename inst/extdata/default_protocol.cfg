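# Default whole-brain two-inversion 3D-EPI protocol (0.8 mm isotropic).
# Timing in ms, flip angles in degrees.

ti1     = 800       # inversion pulse -> k-space centre of block 1 (assumed)
ti2     = 2700      # inversion pulse -> k-space centre of block 2 (assumed)
tr_ir   = 3800      # inversion-recovery cycle duration

alpha1  = 16        # excitation flip angle, readout block 1
alpha2  = 12        # excitation flip angle, readout block 2

nx      = 232
ny      = 232       # phase-encode axis
nz      = 186

seg     = 14        # shots per volume per inversion time
rz      = 3         # CAIPI undersampling along kz
pf      = 0.75      # phase partial Fourier 6/8

n_combo = 4         # read x phase polarity combinations
eps_inv = 1.0       # inversion efficiency
esp_eff = 0.07      # effective echo spacing along PE (ms)

seed      = 1
log_level = info
pe_axis   = 2
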