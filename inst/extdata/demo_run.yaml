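# Demonstration pipeline configuration (desk scale).
# Two matrilineal clans, five generations, strong endogamy; 30 individuals
# excavated and genotyped on 20k pseudo-haploid sites.
seed: 11
sample_n: 30
sim:
  n_clans: 2
  founders_per_clan: 10
  generations: 5
  endogamy_prob: 0.9
  burial_rule: matriclan
  n_sites: 20000
  missing_rate: 0.3
  error_rate: 0.005
kinship:
  window_bp: 1000000
  kin_window_bp: 10000000
  min_overlap: 10
  ibd_min_cM: 12
roh:
  exclude_threshold_cM: 40
clanstats:
  n_perm: 999
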