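# Predator-only learning (case1 wiring) on a reduced lattice.
# Fields mirror case_config() / sim_params() / training_schedule() 1:1.
sim:
  L: 50
  n_pred0: 125
  n_prey0: 500
  bX: 0.8
  bY: 0.1
  fX_init: 1.0
  metabolic_decay: 0.1
  prey_max_age: 100
  T_total: 2000
  seed: 1
mode: evolve
pred_learning:
  gamma: 0.95
  lr: 0.01
  batch_size: 32
  train_period: 50
  updates_per_sweep: 1
  start_mcs: 0
  eps_start: 1.0
  eps_end: 0.05
  eps_anneal_steps: 10000
  reward_scale: 100
  replay_capacity: 10000
  loss_type: pseudo_huber
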