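# Example redesign scheme for the Est30 carboxylesterase scaffold (PDB 1TQH).
#
# Eight lid/pocket positions around the bound substrate may change amino-acid
# type among 16 alternatives; the catalytic machinery (triad S94/H223/D193 and
# the oxyanion-hole residues F25/L95) keeps its types but repacks its side
# chains. Further repack positions are scaffold-specific and are normally
# selected as the residues within 10 angstrom of the bound transition state
# (see neighborsWithin()); add them to `repack` for a full run.

mutable:
  - {chain: A, resno: 26,  native: T, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 122, native: K, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 127, native: M, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 130, native: G, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 167, native: L, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 171, native: I, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 195, native: M, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}
  - {chain: A, resno: 196, native: I, allowed: [A, I, L, M, F, W, "Y", V, C, S, T, K, H, R, "N", Q]}

repack:
  - {chain: A, resno: 94,  native: S}   # nucleophile
  - {chain: A, resno: 223, native: H}   # base
  - {chain: A, resno: 193, native: D}   # acid
  - {chain: A, resno: 25,  native: F}   # oxyanion-hole donor
  - {chain: A, resno: 95,  native: L}   # oxyanion-hole donor

selection:
  bindMax: 0      # ddG_bind must be negative, kcal/mol
  foldMax: 8      # ddG_fold ceiling, kcal/mol
  topTotal: 30    # or ddG_total rank within the top 30
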