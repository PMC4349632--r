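# offertask

Modelling self-control in a sequential offer go/nogo task.

## The problem

How do people arbitrate between the immediate value of an action and its
long-term consequences, when both are paid in the same currency? A
sequential offer task makes this tension precise: on each trial a player
receives 7–9 token offers (worth 3, 5 or 7 tokens each) and may accept
("go") only 4–6 of them, both counts drawn uniformly and hidden. At trial
onset every value is equally likely, but accepting a 5-token offer early
(not on the first offer, and before three rejections have accrued) shifts
every future offer's distribution moderately toward 3s
({0.5, 0.25, 0.25}), and accepting a 7-token offer shifts it severely
({0.9, 0.05, 0.05}). Early in a trial the largest offer is therefore a
trap: its *immediate value* (face value, IR) is highest while its
*long-term value* (EV — face value net of the budget spent and the damage
to future offers) can be negative.

`offertask` implements the full behavioral pipeline for this paradigm, for
researchers in computational cognitive science and decision neuroscience:

- **Task engine** — trial generation, contingency updates, budget
  enforcement, choice-log validation and I/O
  (`simulate_trial()`, `update_m()`, `validate_choice_log()`).
- **Optimal agent** — belief-state dynamic programming over the hidden
  offer/budget counts. With beliefs **O** (offers remaining) and **A**
  (accepts remaining) shifting left as the trial unfolds, the state value is

  SV(**O**, **A**) = Σᵣ Mₘ(r) · max( P(o>1)·SV(**O**′, **A**),
  r + P(o>1)·P(a>1)·SV(**O**′, **A**′) ),

  and the long-term value of accepting an offer of value IR is
  EV = V_AF + IR − V_R (`state_value()`, `long_term_value()`,
  `optimal_policy_table()`), with a brute-force enumeration oracle
  (`brute_force_sv()`).
- **Choice models** — four softmax observation models
  P(go) = 1/(1+e^(−τ·V_A)): immediate (V_A = IR − c), optimal (V_A = EV),
  and one- and three-weight trade-offs
  (V_A = EV·w + (IR − c)(1 − w)), where the weights w ∈ [0, 1] index
  self-control (`model_spec()`, `choice_nll()`).
- **Hierarchical fitting** — Type-II maximum likelihood via
  Expectation-Maximization with Laplace approximations, integrated-BIC
  model comparison and Cox–Snell pseudo-r² (`em_fit()`,
  `compare_models()`, `ibic()`, `pseudo_r2()`).
- **Synthetic data** — group datasets at the study scale (23 subjects ×
  108 trials) from any candidate model, plus parameter-/model-recovery
  studies (`group_design()`, `generate_group()`, `recovery_study()`).
- **Behavioral analysis** — state-wise acceptance grids and robust logistic
  regression of choice on IR and EV (`acceptance_grid()`,
  `robust_logistic()`, `analyze_choices()`).

See `vignettes/offertask-methods.Rmd` for the model details, assumptions
and design decisions.

## Worked example

The solver exposes the task's signature dissociation. At the second offer
with the first offer accepted (uniform distribution, no rejections):

```r
library(offertask)
st <- belief_state(offers_seen = 1, n_accepted = 1, m = 0)
round(sapply(c(3, 5, 7), long_term_value, state = st), 3)
#> [1] -0.776  0.855 -0.359
```

Accepting the 5-token offer gains 0.855 tokens in expectation; the 7-token
offer — the largest immediate payoff on the table — *loses* 0.359 tokens
once its damage to future offers is priced in.

Simulate a group from the three-weight trade-off model and fit it back
hierarchically:

```r
design <- group_design(n_subjects = 12, seed = 1) # 108 trials each, trade3
grp <- generate_group(design)
fit <- em_fit("trade3", grp$log, seed = 1)
fit
#> <em_fit> model trade3: 12 subjects, 9497 free choices
#>   log marginal = -2613.67, iBIC = 5318.93, mean pseudo-r2 = 0.542
#>   EM: 17 iterations, converged
#>   group means (native): tau=3.195 c_int=6.270 w3=0.835 w5=0.926 w7=0.238
```

The recovered group means sit close to the generating ones (sample means
tau 3.371, c_int 6.021, w3 0.802, w5 0.938, w7 0.288). The low `w7`
captures the key individual-difference measure: on 7-token offers, choice
weights immediate over long-term value — the impulsive signature.
`parameter_summary(fit)` tabulates quartiles across subjects,
`compare_models(grp$log)` ranks all four models by iBIC, and
`analyze_choices(grp$log)` produces the acceptance grid and the group
regression report (both IR and EV emerge as significant predictors of
choice on such data).

A thin command-line wrapper over the same functions is available:

```sh
Rscript inst/cli/offertask simulate --seed 1 --out-dir out
Rscript inst/cli/offertask solve --out-dir out
Rscript inst/cli/offertask validate --input out/choices.csv
```

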