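# Example photometry settings for a KB-mirror microprobe station.
# Units: K_E photons/(pA s); g_s uA/V; V_out V; areas mm^2; distances mm;
# resolutions um; theta degrees.
K_E: 2382
g_s: 2
V_out: 4.41
A_active: 127.5
d_sd: 31.2
theta: 45
delta_x: 9.4
delta_y: 12.2
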