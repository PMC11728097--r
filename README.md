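# hippotrial

An in silico randomized trial engine for Alzheimer's disease therapies in
a spiking-network model of the hippocampus.

Memantine (an uncompetitive, voltage-dependent NMDA-receptor antagonist)
and 40 Hz deep brain stimulation (DBS) of the perforant pathway both have
plausible circuit-level mechanisms in the hippocampus, but no clinical
trial has compared their combination head-to-head. `hippotrial` builds a
DG–CA3–CA1 microcircuit of 16-compartment integrate-and-fire neurons with
the shift-register synapse formalism — AMPA register `E(i)`, NMDA register
`M(i)`, summarized potential

    S(i) = ReP + power · ΣE(i)  [ + ΣM(i) while the Mg²⁺ block is removed ]

with resting potential ReP = −80 mV, Mg²⁺-unblock threshold
CaMT = −68 mV, LTP triggered on unblocking, and an excitotoxicity drive
`powerB` ∈ {9, 56.7, 63, 135} replacing the normal `powerA` = 9 on
diseased perforant-path synapses. Virtual AD patients are generated by
progressively disabling EC2 projections onto granule cells, CA3 pyramidal
cells and hippocampal interneurons (moderate or severe stage) and applying
excitotoxicity to the survivors. Therapy operators are mechanistic:
memantine raises the unblock threshold to CaMem ∈ {−68, −65, −63, −55} mV
on every NMDA-bearing synapse; DBS superimposes a 40 Hz spike train on the
nine perforant-path lines. A four-arm randomized trial (untreated AD,
memantine, DBS, DBS+memantine; 20 patients sampled from a 100-network
cohort; 80 endpoint simulations) measures control-normalized spike counts
in DG, CA3 and CA1 and analyzes them with one-way ANOVA and Tukey HSD.

## Worked example

```r
library(hippotrial)

net  <- build_control_network()
prog <- make_ec_program(duration = 2000)      # 16 theta cycles at 8 Hz
ctl  <- run_simulation(net, prog, seed = 999)
ctl
#> <simulation_result> control
#>   raw counts:  DG=326  CA3=268  CA1=127

# one virtual patient: moderate AD, excitotoxicity 63
ad  <- apply_ad_pathology(net, pathology_spec(0.45, 63, "moderate"),
                          seed = 42)
th  <- apply_therapy(ad, prog, therapy_spec("DBS_memantine"))
res <- normalize_counts(run_simulation(th$network, th$program, seed = 1),
                        ctl)
round(res$normalized_counts, 2)
#>   DG  CA3  CA1
#> 1.59 1.13 1.02
```

The raw counts are principal-cell spikes in 1875 ms of counted time (the
first theta cycle is discarded); the normalized counts are relative to the
control network under the non-DBS program, so 1.59 in DG means the
stimulated, treated patient's dentate output exceeds healthy control —
DBS adds input beyond the control stimulus — and the combined therapy
returns this moderate patient's CA3/CA1 output to roughly control level.

A full four-arm trial, calibrated on the untreated-AD arm only:

```r
cal   <- calibrate(trial_design(master_seed = 1))
trial <- run_trial(cal$design)
trial$report          # arm means, 95% CIs, ANOVA, Tukey HSD per region
write_trial_outputs(trial, "trial_out/")
```

A thin command-line driver with `cohort generate`, `simulate`,
`trial run` and `stats` subcommands lives at
`inst/scripts/adtrial.R`:

```sh
Rscript inst/scripts/adtrial.R trial run --seed 42 --out run1/
```

See `vignettes/hippotrial-methods.Rmd` for the model, its assumptions,
the calibration procedure and known limitations.

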