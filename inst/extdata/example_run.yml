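# Example run configuration for the dielcn CLI / run_*() entry points.
# Paths are relative to the working directory; generate the inputs first with
#   dielcn synth --out data --seed 1
condition: Col-0_ambient
observations: data/Col-0_ambient_observations.csv
gas_exchange: data/Col-0_ambient_gas_exchange.csv
activities: data/Col-0_ambient_activities.csv
output_dir: results
rd: 5            # dark respiration magnitude, umol/gFW/h
gamma_star: 45   # CO2 compensation point, ppm
co2_ppm: 450
no3_total: 10    # foliar nitrate, umol/gFW
light_hours: 8
seed: 1
n_runs: 20       # ensemble size
runs_per_step: 10
swarm_size: 24
iterations: 60
sd_band: 1
gate_carboxylates: true
per_cytosol_volume: false
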