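#ifndef GEOMULTINOM_POLYA_GAMMA_H
#define GEOMULTINOM_POLYA_GAMMA_H

double rpg1(double z);

#endif
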