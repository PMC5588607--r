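# Full binary-exposure scenario grid: 2 prevalences x 2 exposure
# associations x 2 effect sizes x 2 mechanisms x 2 mechanism strengths
# = 32 scenarios. Every field of a scenario is listed here with its
# default value; scalar keys apply to all scenarios.
exposure_type: binary
prevalence: [0.10, 0.30]      # target outcome prevalence
assoc: [2, 3]                 # risk ratio RR(X1, X2) between the exposures
beta: [0.6931472, 1.0986123]  # log(2), log(3); applied to both exposures
mechanism: [coordinated, opposite]
lambda: [1, 2]                # strength of MAR dependence on X1
missing_prop: 0.30            # per-variable missingness target
n: 1000                       # rows per simulated dataset
reps: 2000                    # replicates per scenario
m: 20                         # imputations
cycles: 20                    # chained-equation cycles (outcome last)
burn_in: 200                  # data-augmentation burn-in iterations
between: 100                  # iterations between successive imputations
rounding: adaptive            # rounding of continuously imputed binaries
seed: 20170906
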