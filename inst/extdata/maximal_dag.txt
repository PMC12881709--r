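# Maximal DAG over landscape covariates, the latent introduction (p_i) and
# establishment (p_e) probabilities, and pest/disease occurrence (y).
#
# This edge list is CONFIGURATION, not code: it encodes one defensible set of
# assumptions about how elevation (E), distance to park/garden (d_G),
# distance to border control post (d_BCP), vapour pressure deficit (VPD),
# human population (H), urban area (Ur), afforestation (Af), deforestation
# (Df), ancient woodland area (A), conifer area (C_a), broadleaf area (B_a),
# woodland area (W_a), woodland connectivity (W_c) and recreation (R) act on
# introduction and establishment.  Edit it (or pass your own file) to match
# your own assumptions; every downstream routine treats it as data.

latent: p_i, p_e

# terrain and climate
E -> VPD
E -> Ur
E -> W_a
E -> R
VPD -> p_e

# people, infrastructure and movement
H -> Ur
H -> R
H -> p_i
Ur -> R
Ur -> p_i
R -> p_i
d_G -> p_i
d_BCP -> p_i

# land-use change
Af -> W_a
Af -> p_i
Df -> W_a
Df -> p_i

# woodland composition and configuration
A -> B_a
C_a -> W_a
B_a -> W_a
W_a -> W_c
W_c -> p_e
W_a -> p_e
C_a -> p_e
B_a -> p_e
A -> p_e

# occurrence
p_i -> y
p_e -> y
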