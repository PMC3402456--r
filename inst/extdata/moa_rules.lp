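% Mechanism-of-action rules in clingo syntax, for cross-checking the
% native engine: ground together with serialized facts (export_asp()).
% Derived trigger/4 atoms are comparable with the engine per drug
% (presence/absence of a treats conclusion, not per chain: the solver
% assigns one global step ordering, the engine enumerates paths).

#const max_depth = 5.
step(1..max_depth).

% R1: initial step from the drug-target edge.
trigger(Dr, inactivates, P, 1) :- drug(Dr), protein(P), interaction(Dr, inhibits, P).
trigger(Dr, activates,  P, 1) :- drug(Dr), protein(P), interaction(Dr, induces, P).

% R2: propagation along signed protein-protein edges.
trigger(Dr, activates,  P2, S+1) :- trigger(Dr, activates, P1, S), step(S),
                                    protein(P2), interaction(P1, induces, P2).
trigger(Dr, inactivates, P2, S+1) :- trigger(Dr, activates, P1, S), step(S),
                                    protein(P2), interaction(P1, inhibits, P2).
% loss-of-activator propagation (engine policy inactivation_propagation)
trigger(Dr, inactivates, P2, S+1) :- trigger(Dr, inactivates, P1, S), step(S),
                                    protein(P2), interaction(P1, induces, P2).

% R3: expression-state disease association.
trigger(Dr, treats, Dise, S+1) :- trigger(Dr, inactivates, P, S), step(S),
                                  relation(overexpressed(P), associated_with, Dise).
trigger(Dr, treats, Dise, S+1) :- trigger(Dr, activates, P, S), step(S),
                                  relation(underexpressed(P), associated_with, Dise).

% R4/R5: cancer-gene classes.
trigger(Dr, treats, cancer, S+1) :- trigger(Dr, inactivates, P, S), step(S), oncogene(P).
trigger(Dr, treats, cancer, S+1) :- trigger(Dr, activates, P, S), step(S), suppressor(P).

% R6/R7: cancer-related bioprocess classes.
trigger(Dr, treats, cancer, S+1) :- trigger(Dr, inactivates, P, S), step(S),
                                    relation(P, is_associated, Bp),
                                    cancer_promoting_bioprocess(Bp).
trigger(Dr, treats, cancer, S+1) :- trigger(Dr, activates, P, S), step(S),
                                    relation(P, is_associated, Bp),
                                    cancer_resisting_bioprocess(Bp).

% C1-C5: anti-mechanism (promotes) mirrors, for contradiction checks.
trigger(Dr, promotes, cancer, S+1) :- trigger(Dr, activates, P, S), step(S), oncogene(P).
trigger(Dr, promotes, cancer, S+1) :- trigger(Dr, inactivates, P, S), step(S), suppressor(P).
trigger(Dr, promotes, cancer, S+1) :- trigger(Dr, activates, P, S), step(S),
                                      relation(P, is_associated, Bp),
                                      cancer_promoting_bioprocess(Bp).
trigger(Dr, promotes, cancer, S+1) :- trigger(Dr, inactivates, P, S), step(S),
                                      relation(P, is_associated, Bp),
                                      cancer_resisting_bioprocess(Bp).
trigger(Dr, promotes, Dise, S+1) :- trigger(Dr, activates, P, S), step(S),
                                    relation(overexpressed(P), associated_with, Dise).
trigger(Dr, promotes, Dise, S+1) :- trigger(Dr, inactivates, P, S), step(S),
                                    relation(underexpressed(P), associated_with, Dise).

#show trigger/4.
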