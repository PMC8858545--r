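# Example pipeline configuration. Every analysis choice that is a matter of
# convention is an explicit key, so a run is fully described by this file
# plus the seed.
seed: 7
simulate: true
regions: [PFC, HPC]
indices: [pi_preference, pi_recognition]
maxCrlbPct: 50        # CRLB %SD retention threshold (<= keeps)
minN: 5               # inclusion rule threshold
inclusionMode: per_group   # or: total (pooled count strictly > minN)
permutations: 5000
sidedness: two_sided
tVariant: welch       # or: student
rocPositive: WT       # positive class is never defaulted
rocFeatures: flagged  # evaluate features flagged by the screen
rocRegion: PFC
rocIndex: pi_preference
ciMethod: hanley-mcneil
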