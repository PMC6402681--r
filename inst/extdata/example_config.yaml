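# Example beesim configuration: small breeding program, finite-locus
# engine with 400 loci, moderate negative direct-maternal covariance.
#
# Scheme structure -------------------------------------------------------
n_bq_per_year: 300        # new breeding queens (BQs) per year
n_stations_per_year: 4    # mating stations (pseudo sires) set up per year
n_dams_bq: 60             # best two-year-old BQs selected as BQ dams
daughters_per_dam: 5      # daughters per selected BQ dam (60 x 5 = 300)
n_dpq_per_station: 8      # drone-producing queens (DPQs) per station
drones_per_mating: 12     # drones each queen mates with
dam_age_bq: 2             # generation interval on the BQ side (years)
dam_age_dpq: 3            # age of dams of DPQ stations (years)
years: 20                 # simulated years
engine: FL400             # INF, FL200 or FL400
pedigree_mode: exact      # exact (tracked sire drones) or expected

# Genetic parameters (trait units^2) ------------------------------------
sigma2_Ad: 2              # direct (worker) additive variance
sigma2_Am: 1              # maternal (queen) additive variance
sigma_Amd: -0.25          # direct-maternal covariance (r_md = -0.18)
sigma2_E: 1               # residual variance of the performance test

# Run control ------------------------------------------------------------
replicates: 4             # independent runs of this scenario
n_locus_sets: 2           # founder locus sets the runs are spread over
seed: 1                   # master seed; per-replicate seeds derived from it
out: out/fl400_r018_300BQ # output directory (CSVs + manifest)
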