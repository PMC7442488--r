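# npecircuit

Learning negative prediction-error circuits by balancing excitation and
inhibition in a rate-based V1 layer 2/3 microcircuit model.

## The problem

During self-generated movement, the visual input an animal receives is
largely predictable from its own motor commands. Neurons in layer 2/3 of
mouse V1 include *negative prediction-error* (nPE) cells that stay silent
while sensation matches prediction (closed-loop "feedback"), stay silent
for unpredicted-but-present input ("playback"), and fire when a predicted
input fails to arrive ("mismatch"). `npecircuit` implements a rate-based
circuit model — excitatory two-compartment pyramidal cells (PCs) plus
PV, SOM and VIP interneurons — in which such neurons are not wired by
hand but *emerge* through inhibitory synaptic plasticity that balances
excitation and inhibition across multiple pathways. The package is aimed
at computational neuroscientists who want to reproduce, probe or extend
the circuit-level theory: which interneurons must receive which inputs,
which synapses must be plastic, and what simulated optogenetic
manipulations reveal about the underlying configuration.

## The model in brief

The PC soma follows a rectified rate equation
τ_E dr_E/dt = −r_E + [I − Θ]₊ with total somatic input

    I = λ_D [I_D + c]₊ + (1 − λ_E) I_E,
    I_E = x_E − w_EP r_P,
    I_D = x_D − w_DS r_S + w_DE r_E,

where the dendritic bracket keeps excess dendritic inhibition from
reaching the soma and `c` is a calcium-spike current triggered when total
dendritic drive crosses a threshold. PV/SOM/VIP units are rectified
linear units with a fast time constant. For a homogeneous network whose
dendrites are inhibited during feedback and playback, requiring PCs to
remain at baseline in both phases fixes two interneuron pathways:

    w_PS = V_P + w_VS·M_P − (1 + w_PP)/w_EP · V_E
    w_PV = w_SV·w_PS + (1 − w_SV·w_VS)·M_P

(`solve_constraints()`), where V_X/M_X flag visual/motor input to
population X. Plastic networks reach this balance by learning: inhibitory
Hebbian rules on PV→soma and SOM→dendrite synapses, and either an
approximate backpropagation-of-error rule, a local recurrent-drive
approximation, or a PV-homeostatic rule on the SOM/VIP→PV synapses.

## Worked example

```r
library(npecircuit)

# build the default plastic network and train it on quasi-natural
# sensorimotor experience (alternating feedback/playback, amplitudes
# uniform on [0, 7] 1/s, 1-s phases interleaved with baselines)
net     <- build_network(plastic = TRUE, seed = 1)
stimuli <- training_sequence("qt", n_stimuli = 4000, seed = 2)
trained <- train_network(net, stimuli, plasticity_config())
glance(trained)
#> # A tibble: 1 × 12
#>    n_pc  n_pv n_som n_vip   v_e   v_p   m_p f_som plastic trained converged
#>   <int> <int> <int> <int> <int> <int> <int> <dbl> <lgl>   <lgl>   <lgl>
#> 1    70    10    10    10     1     1     0     1 TRUE    TRUE    TRUE
#> # ℹ 1 more variable: n_stimuli <dbl>

# probe with the feedback / mismatch / playback triplet at 7 1/s
sim <- simulate_protocol(trained, test_triplet(7))
cls <- classify_pcs(sim)
table(cls$label)
#>
#>           nPE           pPE      baseline suppressed_MM         other
#>            70             0             0             0             0
#>     undefined
#>             0

# every PC responds only to mismatch: mean dR/R per phase
colMeans(cls[, c("fb", "mm", "pb")])
#>          fb          mm          pb
#> -0.04528368  1.06855076 -0.01927816

# the learned SOM->PV / VIP->PV weights recover the analytic balance
check_balance(trained)
#> # A tibble: 3 × 5
#>   quantity learned analytic reference rel_deviation
#>   <chr>      <dbl>    <dbl>     <dbl>         <dbl>
#> 1 w_ps       0.502    0.511     0.511        0.0178
#> 2 w_pv       0.314    0.328     0.328        0.0446
#> 3 dendrite   0        0         7            0
```

`table(cls$label)` counts each PC's response type: an `nPE` label means
ΔR/R exceeds +20% in mismatch while staying within ±10% of baseline in
feedback and playback. `check_balance()` compares the
population-summed learned weights against the constraint solution
evaluated at the network's own effective w_PP and w_EP, plus the residual
(uncancelled) dendritic activity during feedback relative to the motor
drive.

Other entry points: `opto_fingerprint()` (simulated PV/SOM/VIP
in-/activation), `current_decomposition()` (somatic E/I currents in pA),
`run_experiment()` / `inst/cli/npe-circuit.R` (configured end-to-end
runs), `autoplot()`, `plot_response_heatmap()`, `plot_currents()`.

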