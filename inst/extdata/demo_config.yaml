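# Demo synthetic trial with a strong qualitative treatment-by-baseline
# interaction: childhood trauma, female gender and previous suicide
# attempts favor ESC/CM; older age favors CBASP. gamma = -delta/2 makes
# the two arms' predicted outcome lines slope against each other so that
# matched patients improve markedly on either side of the cross-point.
# Calibrated so pairwise moderator effect sizes land around |0.2|-|0.3|
# and the composite effect size around 0.5-0.7 at arm sizes 27/26.
seed: 42
sigma: 15
mu0: -25
tau: 18
delta:
  age: -1.2
  trauma: 30.0
  female: 20.0
  suicide_attempts: 15.0
gamma:
  age: 0.6
  trauma: -15.0
  female: -10.0
  suicide_attempts: -7.5
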