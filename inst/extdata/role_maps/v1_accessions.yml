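# Curated chain-to-role template maps for the five V-ATPase depositions
# (A3B3: 3VR2 apo, 3VR3 two AMP-PNP; A3B3DF: 3VR4 apo, 3VR6 two AMP-PNP,
# 5KNB two ADP).
#
# CURATED TEMPLATES, NOT DERIVED TRUTH: positional role naming (which A
# subunit is A_DP/A_TP/A_E) differs between depositions and between
# naming conventions of different groups, and the correspondence cannot
# be inferred from the coordinate files alone.  Verify each assignment
# against the deposition's own chain annotation and the ligand occupancy
# (the DP and TP sites are the nucleotide-bound ones; the E site is
# empty) before use, and edit in place.  The entries below follow the
# common A/B/C = catalytic, D/E/F = non-catalytic, G/H = central-shaft
# chain layout of these depositions.

3vr2:
  role_map: {A: A_DP, B: A_TP, C: A_E, D: B_DP, E: B_TP, F: B_E}

3vr3:
  role_map: {A: A_DP, B: A_TP, C: A_E, D: B_DP, E: B_TP, F: B_E}
  site_ligands: {A_DP: ATP, A_TP: ATP}

3vr4:
  role_map: {A: A_DP, B: A_TP, C: A_E, D: B_DP, E: B_TP, F: B_E, G: DF}

3vr6:
  role_map: {A: A_DP, B: A_TP, C: A_E, D: B_DP, E: B_TP, F: B_E, G: DF}
  site_ligands: {A_DP: ATP, A_TP: ATP}

5knb:
  role_map: {A: A_DP, B: A_TP, C: A_E, D: B_DP, E: B_TP, F: B_E, G: DF}
  site_ligands: {A_DP: ADP, A_TP: ADP}
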