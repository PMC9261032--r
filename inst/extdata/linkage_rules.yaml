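# Bonding rules for lignin inter-monomer linkages.
#
# Atomic indices follow the standard monolignol numbering: ring carbons 1-6,
# side chain alpha = 7, beta = 8, gamma = 9, phenolic oxygen (4-O) = 10,
# gamma hydroxyl oxygen = 11, methoxy O/C = 12/13 (3-position) and 14/15
# (5-position, syringyl only).  Linkage names that contain an "O" bond
# through the 4-O ether oxygen; an index of 4 in a pair therefore denotes
# the phenolic oxygen attached to C4.
#
# The file is editable: adding a linkage type (e.g. b-1) requires a pair
# set, retirement rules here and a matching bond-transform in the package.
# b-5 is directional: the beta radical lives on the chain end (C1 = 8) and
# couples to the C5 of a fresh phenolic unit (C2 = 5); a unit buried in the
# chain cannot supply the phenoxy radical a beta-5 coupling needs.  The
# other pair sets are symmetric.
linkage_pairs:
  4-O-5: [[4, 5], [5, 4]]
  a-O-4: [[4, 7], [7, 4]]
  b-O-4: [[4, 8], [8, 4]]
  5-5:   [[5, 5]]
  b-5:   [[8, 5]]
  b-b:   [[8, 8]]
# Atomic indices at which a free monomer of each type can donate a bonding
# atom (C1).  Syringyl is blocked at 5 by the second methoxy group.
feasible_c1:
  H: [4, 5, 7, 8]
  G: [4, 5, 7, 8]
  S: [4, 7, 8]
# Bonding availability withdrawn on each side once a linkage forms, keyed by
# the atomic index the side donated.  The 7/8 pair always retires together:
# forming any beta-family or alpha bond consumes the 7-8 side-chain double
# bond, so neither position can enter a later linkage.  The 5-side of a b-5
# also loses its 4-O (consumed by the coumaran ring).
retired_on_bond:
  4-O-5: {"4": [4], "5": [5]}
  a-O-4: {"4": [4], "7": [7, 8]}
  b-O-4: {"4": [4], "8": [7, 8]}
  5-5:   {"5": [5]}
  b-5:   {"5": [4, 5], "8": [7, 8]}
  b-b:   {"8": [7, 8]}
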