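name: knee_oa_2020
horizon: 6 months (no discounting)
parameters:
- name: sam_device_cost
  base: 4635.0
  low: 2000.0
  high: 6000.0
  role: cost
  dist:
    kind: triangular
    low: 2000.0
    mode: 4635.0
    high: 6000.0
  note: average reimbursement price of the SAM unit
- name: pt_session_cost
  base: 41.79999999999999716
  low: 25.0
  high: 60.0
  role: cost
  dist:
    kind: triangular
    low: 25.0
    mode: 41.79999999999999716
    high: 60.0
  note: cost per 15-min PT session
- name: n_pt_sessions
  base: 68.40000000000000568
  low: 48.0
  high: 96.0
  role: count
  dist:
    kind: triangular
    low: 48.0
    mode: 68.40000000000000568
    high: 96.0
  note: expected 15-min PT sessions over 6 months; 2-4 sessions/visit (reconstructed)
- name: p_sam_success
  base: 0.69999999999999996
  low: 0.55000000000000004
  high: 0.84999999999999998
  role: probability
  dist:
    kind: uniform
    low: 0.55000000000000004
    high: 0.84999999999999998
  note: P(pain relief on SAM sufficient to start PT) (reconstructed)
- name: p_soc_success
  base: 0.55000000000000004
  low: 0.40000000000000002
  high: 0.69999999999999996
  role: probability
  dist:
    kind: uniform
    low: 0.40000000000000002
    high: 0.69999999999999996
  note: P(pain relief on first-line topical NSAID) (reconstructed)
- name: soc_first_line_cost
  base: 240.0
  low: 120.0
  high: 360.0
  role: cost
  dist:
    kind: triangular
    low: 120.0
    mode: 240.0
    high: 360.0
  note: 6-month topical NSAID supply + visits (reconstructed)
- name: escalation_cost
  base: 900.0
  low: 500.0
  high: 1500.0
  role: cost
  dist:
    kind: triangular
    low: 500.0
    mode: 900.0
    high: 1500.0
  note: steroid/HA injections + visits for non-responders (reconstructed)
- name: e_sam_pt
  base: 0.60999999999999999
  low: 0.45000000000000001
  high: 0.75
  role: effect
  dist:
    kind: triangular
    low: 0.45000000000000001
    mode: 0.60999999999999999
    high: 0.75
  note: effect size, SAM responder with PT (reconstructed)
- name: e_sam_no_pt
  base: 0.31
  low: 0.20000000000000001
  high: 0.41999999999999998
  role: effect
  dist:
    kind: triangular
    low: 0.20000000000000001
    mode: 0.31
    high: 0.41999999999999998
  note: effect size, SAM non-responder (reconstructed)
- name: e_soc_pt
  base: 0.47999999999999998
  low: 0.34999999999999998
  high: 0.60999999999999999
  role: effect
  dist:
    kind: triangular
    low: 0.34999999999999998
    mode: 0.47999999999999998
    high: 0.60999999999999999
  note: effect size, SOC responder with PT (reconstructed)
- name: e_soc_no_pt
  base: 0.28000000000000003
  low: 0.17999999999999999
  high: 0.38
  role: effect
  dist:
    kind: triangular
    low: 0.17999999999999999
    mode: 0.28000000000000003
    high: 0.38
  note: effect size, SOC non-responder (reconstructed)
- name: pt_util_sam
  base: 0.90000000000000002
  low: 0.90000000000000002
  high: 0.90000000000000002
  role: count
  note: PT utilization multiplier, SAM arm (reconstructed)
- name: pt_util_soc
  base: 1.64650008860535157
  low: 1.64650008860535157
  high: 1.64650008860535157
  role: count
  note: PT utilization multiplier, SOC arm; reverse-engineered from the $88 session-price
    break-even (reconstructed)
- name: pt_util_sam_late
  base: 2.0
  low: 2.0
  high: 2.0
  role: count
  note: PT utilization multiplier, later SAM+PT arm (reconstructed)
- name: pt_util_soc_late
  base: 2.5
  low: 2.5
  high: 2.5
  role: count
  note: PT utilization multiplier, later NSAID+PT arm (reconstructed)
- name: e_sam_pt_late
  base: 0.77000000000000002
  low: 0.65000000000000002
  high: 0.89000000000000001
  role: effect
  dist:
    kind: triangular
    low: 0.65000000000000002
    mode: 0.77000000000000002
    high: 0.89000000000000001
  note: effect size, later-stage SAM+PT pathway
- name: e_soc_pt_late
  base: 0.46999999999999997
  low: 0.34999999999999998
  high: 0.58999999999999997
  role: effect
  dist:
    kind: triangular
    low: 0.34999999999999998
    mode: 0.46999999999999997
    high: 0.58999999999999997
  note: effect size, later-stage NSAID+PT pathway
- name: resid_cost_sam
  base: 1162.79199999999946158
  low: 1162.79199999999946158
  high: 1162.79199999999946158
  role: cost
  note: residual 6-month arm cost, SAM (calibrated)
- name: resid_cost_soc
  base: 929.45866666666734091
  low: 929.45866666666734091
  high: 929.45866666666734091
  role: cost
  note: residual 6-month arm cost, SOC (calibrated)
- name: resid_cost_sam_late
  base: 3613.76000000000021828
  low: 3613.76000000000021828
  high: 3613.76000000000021828
  role: cost
  note: residual 6-month arm cost, later SAM+PT (calibrated)
- name: resid_cost_soc_late
  base: 1906.2000000000007276
  low: 1906.2000000000007276
  high: 1906.2000000000007276
  role: cost
  note: residual 6-month arm cost, later NSAID+PT (calibrated)
- name: resid_effect_sam
  base: 0.0
  low: 0.0
  high: 0.0
  role: effect
  note: residual arm effect, SAM (calibrated)
- name: resid_effect_soc
  base: 0.0
  low: 0.0
  high: 0.0
  role: effect
  note: residual arm effect, SOC (calibrated)
tree:
  kind: decision
  label: knee OA 6-month management
  strategies:
  - label: SAM
    node:
      kind: chance
      label: pain response to SAM
      branches:
      - prob: p_sam_success
        node:
          kind: terminal
          label: 'SAM responder: PT initiated'
          cost: sam_device_cost + pt_session_cost * n_pt_sessions * pt_util_sam +
            resid_cost_sam
          effect: e_sam_pt + resid_effect_sam
      - prob: 1 - p_sam_success
        node:
          kind: terminal
          label: 'SAM non-responder: escalation, delayed PT'
          cost: sam_device_cost + pt_session_cost * n_pt_sessions * pt_util_sam +
            escalation_cost + resid_cost_sam
          effect: e_sam_no_pt + resid_effect_sam
  - label: SOC
    node:
      kind: chance
      label: pain response to first-line topical NSAID
      branches:
      - prob: p_soc_success
        node:
          kind: terminal
          label: 'SOC responder: PT initiated'
          cost: soc_first_line_cost + pt_session_cost * n_pt_sessions * pt_util_soc
            + resid_cost_soc
          effect: e_soc_pt + resid_effect_soc
      - prob: 1 - p_soc_success
        node:
          kind: terminal
          label: 'SOC non-responder: escalation, delayed PT'
          cost: soc_first_line_cost + pt_session_cost * n_pt_sessions * pt_util_soc
            + escalation_cost + resid_cost_soc
          effect: e_soc_no_pt + resid_effect_soc
  - label: SAM+PT (later)
    node:
      kind: terminal
      label: 'later-stage: SAM responder continuing PT'
      cost: sam_device_cost + pt_session_cost * n_pt_sessions * pt_util_sam_late +
        resid_cost_sam_late
      effect: e_sam_pt_late
  - label: NSAID+PT (later)
    node:
      kind: terminal
      label: 'later-stage: NSAID responder continuing PT'
      cost: soc_first_line_cost + pt_session_cost * n_pt_sessions * pt_util_soc_late
        + resid_cost_soc_late
      effect: e_soc_pt_late
comparisons:
- new: SAM
  standard: SOC
- new: SAM+PT (later)
  standard: NSAID+PT (later)
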