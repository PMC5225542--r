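population,region
abrolhos,indian
gbr,pacific
cook,pacific
fiji,pacific
frpoly,pacific
indonesia,pacific
iran,indian
png,pacific
solomon,pacific
taiwan,pacific
tan_mafia,indian
tan_mtwara,indian
tonga,pacific
vietnam,pacific
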