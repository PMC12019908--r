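label	canonical
cytoplasmic	cytoplasmic
cytoplasm	cytoplasmic
cytosol	cytoplasmic
cytoplasmicmembrane	cytoplasmic_membrane
innermembrane	cytoplasmic_membrane
plasmamembrane	cytoplasmic_membrane
membrane	cytoplasmic_membrane
periplasmic	periplasmic
periplasm	periplasmic
cellwall	cell_wall
cellwallandsurface	cell_wall
surface	cell_wall
outermembrane	outer_membrane
extracellular	extracellular
extracellularspace	extracellular
secreted	extracellular
unknown	unknown
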