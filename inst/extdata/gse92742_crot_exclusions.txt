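# Curated exclusions for the CROT screen:
# IKK-2-inhibitor-V — IKK-beta deficiency increases vascular calcification,
#   so an IKK-2 inhibitor is an implausible calcification therapeutic.
# mebendazole, D-64131 — microtubule destabilizers; microtubule
#   stabilization attenuates calcification via osteogenic signaling.
IKK-2-inhibitor-V
mebendazole
D-64131
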