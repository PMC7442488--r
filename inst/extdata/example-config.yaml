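# Example experiment configuration: quasi-natural training of the
# default plastic network, then the feedback/mismatch/playback probe.
preset: custom
sizes:
  n_pc: 70
  n_pv: 10
  n_som: 10
  n_vip: 10
input:
  v_e: 1
  v_p: 1
  m_p: 0
  f_som: 1.0
plastic: true
paradigm: qt
n_stimuli: 3000
stim_max: 7.0
plasticity:
  variant: backprop
dt_test: 0.1
dt_train: 1.0
seed_connectivity: 1
seed_stimuli: 2
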