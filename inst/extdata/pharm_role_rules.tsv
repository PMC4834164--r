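# Ordered ligand pharmacophore role rules: first matching pattern wins.
# pattern names are structural predicates implemented in the package;
# roles are comma-separated members of {DONOR, ACCEPTOR, DONOR_OR_ACCEPTOR,
# CATION, ANION, HYDROPHOBE}.
pattern	roles
o_anion	ACCEPTOR,ANION
o_carbonyl	ACCEPTOR
o_hydroxyl	DONOR,ACCEPTOR
o_ether	ACCEPTOR
n_cation	DONOR,CATION
n_primary	DONOR
n_secondary	DONOR_OR_ACCEPTOR
n_tertiary	ACCEPTOR
s_thiol	DONOR
s_thioether	ACCEPTOR
c_apolar	HYDROPHOBE
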