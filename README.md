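# comra

Context-based simulation and analysis of individual and collaborative free
recall.

## The problem

A group of people recalling a studied word list together reliably remembers
*less* than the same number of people recalling alone — the **collaborative
inhibition** effect. `comra` implements a retrieved-context account of this
effect: each individual is a CMR-style (Context Maintenance and Retrieval)
memory model whose slowly drifting context vector is bound to items at study
and cues retrieval at test; in a collaborative group, whenever one member
recalls a novel item, every other active member attends to it with
probability `p_cue` and drifts their own context toward it, exactly as if
they had recalled it themselves. Nothing else differs between conditions.
Listening makes group members' contexts converge, convergence constrains
where each member can search, and inhibition *emerges* — no suppression
mechanism is assumed.

The package is for computational memory researchers who want to simulate the
turn-taking group free-recall protocol (randomized per-individual study
orders; recall in rounds; novel recalls broadcast; a permanent "I can't
recall anymore" option), compute the standard behavioral statistics, analyze
context dynamics, and fit the model.

## The model

For unit context `c` and unit input `c_in`, context drifts as

    c' = rho * c + beta * c_in,
    rho = sqrt(1 + beta^2 * ((c . c_in)^2 - 1)) - beta * (c . c_in),

so `||c'|| = 1`. At study, item `i` at position `p` is bound to the
pre-drift context by Hebbian outer products
(`M_fc += gamma_fc * c  f_i'`, `M_cf += phi(p) * gamma_cf * f_i c'`,
primacy boost `phi(p) = 1 + phi_s exp(-phi_d (p-1))`), after which context
drifts toward the item's semantic direction at rate `beta_enc`. `M_cf` is
pre-loaded with semantic associations `s_sem * cos(i, j)` from an embedding
space. At test, activations are `a = M_cf c` (floored at `a_min`), the next
recall is sampled with probability `a_i^tau / sum a_j^tau` over items not
yet recalled by that agent, recall stops at output position `k` with
probability `min(1, (theta0/eps_d) exp(theta_r k))`, and each recalled —
or attended-to — item drifts context toward its stored representation at
rate `beta_rec`.

## Worked example

```r
library(comra)

# a 20-word list embedded in 4 semantic clusters
space <- generate_synthetic_space(n_items = 20, dim = 16, n_clusters = 4,
                                  cluster_spread = 0.25, seed = 42)
params <- cmr_params()   # p_cue = 0.2 by default

# paired nominal / collaborative triads (same study orders, same stop decisions)
nominal <- lapply(1:100, function(g)
  simulate_nominal_group(space, params, group_size = 3, seed = g))
collab <- lapply(1:100, function(g)
  simulate_collaborative_group(space, params, group_size = 3, seed = g))

collaborative_inhibition(list("3" = nominal), list("3" = collab))
#>   group_size nominal_mean collaborative_mean inhibition         se
#> 1          3       0.5945              0.542     0.0525 0.02839668

semantic_similarity_by_lag(collab, space, max_lag = 4, scope = "own")
#>   lag      mean          se n_pairs
#> 1   1 0.4575732 0.005278260    1379
#> 2   2 0.3253209 0.007277849    1139
#> 3   3 0.2296607 0.008306173     928
#> 4   4 0.1644152 0.009153382     747
```

Nominal triads recalled 59.5% of the list, collaborative triads 54.2% — a
collaborative inhibition of 5.3 points (the groups are seed-paired, so the
difference isolates the listening mechanism). Recalls are semantically
clustered: the mean cosine between items recalled one output position apart
(0.458) is far higher than four positions apart (0.164). The context
mechanism behind the inhibition is directly measurable:

```r
conv <- sapply(collab, function(t)
  context_convergence(context_trajectories(t, length_out = 10)))
conv_nom <- sapply(nominal, function(t)
  context_convergence(context_trajectories(t, length_out = 10)))
sprintf("mean context convergence: collaborative %+.3f, nominal %+.3f",
        mean(conv), mean(conv_nom))
#> "mean context convergence: collaborative +0.066, nominal -0.058"
```

Collaborating members' contexts grow *more* similar over the first ten
outputs, while independent recallers' contexts drift apart.

## Command line

```sh
Rscript inst/cli/comra.R gen-space --n-items 60 --dim 32 --out space.txt
Rscript inst/cli/comra.R simulate --condition collaborative --group-size 4 \
    --n-groups 24 --seed 7 --out runs/
Rscript inst/cli/comra.R figures --preset desk --seed 1 --out figures/
```

See `vignettes/comra-methods.Rmd` for the model assumptions, parameter
defaults and their calibration, the synthetic-data generator's scope, and
known limitations.
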