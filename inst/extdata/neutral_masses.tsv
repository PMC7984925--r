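component	formula	neutral_monoisotopic_mass
Catalpol	C15H22O10	362.1213
Aucubin	C15H22O9	346.1264
Gallic acid	C7H6O5	170.0215
Hydroxysafflor yellow A	C27H32O16	612.1690
Amygdalin	C20H27NO11	457.1584
Echinacoside	C35H46O20	786.2583
Calycosin-7-O-β-D-glucoside	C22H22O10	446.1213
Acteoside	C29H36O15	624.2054
Ononin	C22H22O9	430.1264
Calycosin	C16H12O5	284.0685
Astragaloside IV	C41H68O14	784.4609
Formononetin	C16H12O4	268.0736
Rhein	C15H8O6	284.0321
Emodin	C15H10O5	270.0528
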