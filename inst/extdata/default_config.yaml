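# Default risk-parameter configuration: six metals with oral reference
# doses (mg/kg bw/day) and two population groups with their parameter
# distributions. Body-weight lognormals carry an explicit coefficient of
# variation (0.10) because only a central value is measured; averaging
# time follows the non-carcinogenic convention AT = ED x 365 days.
source: IWW
vegetables: [Ladyfinger, Pumpkin, Onion, Green pepper]
metals:
  - {name: Fe, rfd: 0.7, who_limit: 5.00}
  - {name: Pb, rfd: 0.004, who_limit: 0.01}
  - {name: Cr, rfd: 1.5, who_limit: 0.05}
  - {name: Ni, rfd: 0.02, who_limit: 0.07}
  - {name: Mn, rfd: 0.033, who_limit: 0.20}
  - {name: Co, rfd: 0.090, who_limit: 0.025}
groups:
  - name: children
    bw: {family: lognormal, mean: 32.7, cv: 0.10}
    ed: {family: uniform, min: 1, max: 7}
    ef: {family: triangular, min: 180, mode: 345, max: 365}
    cf: 0.085
    at_rule: {rule: ed_times_365}
    ir:
      Ladyfinger: {family: normal, mean: 0.0155, sd: 0.01}
      Pumpkin: {family: normal, mean: 0.045, sd: 0.01}
      Onion: {family: normal, mean: 0.0058, sd: 0.01}
      Green pepper: {family: normal, mean: 0.0058, sd: 0.01}
  - name: adults
    bw: {family: lognormal, mean: 73.5, cv: 0.10}
    ed: {family: uniform, min: 26, max: 70}
    ef: {family: triangular, min: 180, mode: 345, max: 365}
    cf: 0.085
    at_rule: {rule: ed_times_365}
    ir:
      Ladyfinger: {family: normal, mean: 0.058, sd: 0.01}
      Pumpkin: {family: normal, mean: 0.0648, sd: 0.01}
      Onion: {family: normal, mean: 0.0218, sd: 0.01}
      Green pepper: {family: normal, mean: 0.0218, sd: 0.01}
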