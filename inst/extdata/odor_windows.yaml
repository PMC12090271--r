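# Steady-state averaging windows (minutes from odor application), per odor.
# The behavioral time course differs between odors, so the window over which
# the per-frame CoM is averaged is odor-specific. User-overridable.
benzaldehyde: [20, 60]
propionic acid: [5, 25]
R-limonene: [0, 60]
AITC: [20, 60]
citronellal: [20, 60]
isovaleric acid: [5, 25]
lemongrass: [20, 60]
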