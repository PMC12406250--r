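Fixture input tables
====================

head_groups.csv / tail_groups.csv
  Building-block definitions for the head (P1) and tail (P2) generation
  problems of the worked case studies: group name, fragment SMILES, group
  valence, per-connection atom indices and capacities ("final" = last atom
  of the SMILES), and the maximum number of occurrences per fragment.

  Provenance note: the original tabulations of these inputs lost bond-order
  characters in typesetting (a ketone printed as "CO", an aromatic ring as
  "C1CCCCC1", and so on). The `smiles` column carries chemically corrected
  strings (C=O, c1ccccc1, OS(=O)(=O)[O-], ...; stereocenter annotations are
  dropped from the glycoside); the `smiles verbatim` column preserves the
  strings exactly as printed, for reference. The corrected column is the
  one read by the package.

objectives_case1.csv / objectives_case2.csv
  Multiobjective optimization configurations: which property models act as
  objectives (with direction) and which as hard constraints (with cut-off
  values; "inf" = unbounded). Case 1 minimizes synthetic accessibility and
  log(CMC) while maximizing biodegradability; case 2 minimizes log(CMC)
  while maximizing log(LC50), i.e. minimizing aquatic toxicity.
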