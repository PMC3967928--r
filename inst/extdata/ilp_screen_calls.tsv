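# Curated high-confidence phenotype calls for the 35-mutant C. elegans ILP
# deletion panel, one row per (mutant, assay) hit, from the published screen
# summary. direction: +1 = more dauers / longer survival or span than control.
# Calls visible only in the full published dataset may be absent here.
ilp	assay	level	direction
daf-28	dauer_entry	high	1
ins-33	dauer_entry	high	1
ins-35	dauer_entry	high	1
ins-10	dauer_entry	high	1
ins-12	dauer_entry_daf2	high	-1
ins-4	dauer_entry_daf2	high	1
ins-14	dauer_entry_daf2	high	1
ins-33	dauer_entry_daf2	high	1
ins-35	dauer_entry_daf2	high	1
ins-5	dauer_entry_daf28	high	1
ins-8	dauer_entry_daf28	high	1
ins-11	dauer_entry_daf28	high	1
ins-21	dauer_entry_daf28	high	1
ins-22	dauer_entry_daf28	high	1
ins-23	dauer_entry_daf28	high	1
ins-26	dauer_entry_daf28	high	1
ins-3	dauer_entry_daf28	high	-1
ins-13	dauer_entry_daf28	high	-1
ins-6	dauer_entry_daf28	high	1
ins-1	dauer_entry_daf28	high	-1
ins-11	dauer_exit	high	1
ins-12	dauer_exit	high	1
ins-15	dauer_exit	high	1
ins-18	dauer_exit	high	1
ins-10	dauer_exit	high	1
ins-23	dauer_exit	high	-1
daf-28	dauer_exit	high	1
ins-6	dauer_exit	high	1
ins-23	lifespan	high	1
ins-6	lifespan	high	1
ins-1	lifespan	high	1
ins-27	thermotolerance	high	1
ins-23	thermotolerance	high	1
ins-1	thermotolerance	high	1
ins-27	pathogen_resistance	high	1
ins-31	pathogen_resistance	high	1
ins-20	pathogen_resistance	high	-1
daf-28	reproductive_span	high	1
ins-6	reproductive_span	high	1
ins-13	reproductive_span	high	1
ins-31	reproductive_span	high	1
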