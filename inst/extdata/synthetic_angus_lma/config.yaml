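n_labs: 3.0
technicians_per_lab: 2.0
cgs_per_technician: 2.0
animals_per_cg: 4.0
n_sires: 8.0
n_dams: 24.0
sire_sharing: 1.0
sigma2_t:
- 53.98
- 53.98
- 53.98
sigma2_c:
- 124.13
- 124.13
- 124.13
sigma2_a: 16.87
sigma2_e:
- 35.06
- 35.06
- 35.06
mu:
- 78.2
- 78.2
- 78.2
breed: ANGUS
trait: LMA
generations: 3.0
cg_size_dispersion: ~
seed: 60930
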