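# Analysis configuration for a synthetic agonist-like trajectory
# (residue numbering: helix h spans h*100+1 .. h*100+26, anchor x.50 at index 13).
structure: agonist.pdb      # multi-model PDB: topology + frames
dt_ns: 1.0

helices:
  - {helix_id: 1, start: 101, end: 126, anchor_seq: 113, intracellular_end: start}
  - {helix_id: 2, start: 201, end: 226, anchor_seq: 213, intracellular_end: start}
  - {helix_id: 3, start: 301, end: 326, anchor_seq: 313, intracellular_end: start}
  - {helix_id: 4, start: 401, end: 426, anchor_seq: 413, intracellular_end: start}
  - {helix_id: 5, start: 501, end: 526, anchor_seq: 513, intracellular_end: start}
  - {helix_id: 6, start: 601, end: 626, anchor_seq: 613, intracellular_end: start}
  - {helix_id: 7, start: 701, end: 726, anchor_seq: 713, intracellular_end: start}

switches:
  - {residue: 220, angle: chi1, bins: default, min_dwell: 50, filter_window: 21}
  - {residue: 611, angle: chi2, bins: toggle, min_dwell: 50, filter_window: 21}
  - {residue: 607, angle: chi1, bins: default, min_dwell: 50, filter_window: 21}

hydration:
  - {label: "D2.50", selection: "resid 213 and heavy", cutoff: 4.0}

kink: {helix_id: 7, pivot: "7.50", window: 7, smooth_frames: 21}

rmsd: {selection: "backbone", reference_frame: 1}

clustering: {helix_ids: [3, 6, 7], k: 3, seed: 1, end_length: 4}
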