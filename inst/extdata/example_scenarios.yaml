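# Small Monte-Carlo scenario list for the `simulate` CLI verb.
# PF_true = (limit - mu)/sigma (smaller-the-better) spans below / at /
# above the required level k = 6.
- true_mu: 590.6
  true_sigma: 1.84
  n_per_sample: 10
  n_replicates: 2000
  seed: 11
  spec:
    item_id: cardio_low
    orientation: smaller_better
    limit: 598
    k: 6
- true_mu: 587.0
  true_sigma: 1.84
  n_per_sample: 10
  n_replicates: 2000
  seed: 12
  spec:
    item_id: cardio_at_k
    orientation: smaller_better
    limit: 598.04
    k: 6
- true_mu: 584.0
  true_sigma: 1.84
  n_per_sample: 10
  n_replicates: 2000
  seed: 13
  spec:
    item_id: cardio_high
    orientation: smaller_better
    limit: 598
    k: 6
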