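# Simplified high-osmolarity-glycerol (HOG) pathway oscillator, qualitative
# variant (absolute contingencies). SYNTHETIC transcription: a minimal
# two-module negative-feedback loop; assumptions are documented in the
# package vignette.
#
# Turgor sensing: Sln1 is in its active, turgor-bound conformation only
# while glycerol accumulation (driven by phosphorylated Hog1) keeps turgor
# up; the interaction decays as soon as the drive stops.
Sln1_ppi_Turgor; ! Hog1-{P}
# Phosphotransfer module: active Sln1 keeps Ssk1 phosphorylated; without
# the turgor signal the phosphorelay runs dry and Ssk1-{P} is lost.
Sln1_P+_Ssk1; ! Sln1--Turgor
Ypd1_P-_Ssk1; x Sln1--Turgor
# MAP kinase module: Pbs2 phosphorylates Hog1 only while the
# phosphotransfer module is inactive; Ptp2 dephosphorylates Hog1 when the
# phosphotransfer module is back on.
Pbs2_P+_Hog1; x Ssk1-{P}
Ptp2_P-_Hog1; ! Ssk1-{P}
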