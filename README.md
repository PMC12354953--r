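# molfewshot

Few-shot molecular property prediction with a Bayesian hypernetwork
meta-learner.

## The problem

Molecule-property matrices from assay panels (toxicity endpoints, side
effects, bioassays) are sparse: each property has labels for only a small,
uneven subset of molecules, and new assays arrive with a handful of
measurements. `molfewshot` treats every property column as a binary *task*
and meta-learns across tasks so that a new task can be adapted to from K
labeled molecules per class. It is aimed at computational chemists and
method developers who want a complete, dependency-light, fully inspectable
R implementation of this model family — every gradient is hand-derived and
finite-difference audited.

## The model

Molecules are kekulized and featurized into typed atom-bond graphs, then
encoded by a graph isomorphism network whose messages carry bond
information:

    h_v^(0) = f_atom(v) + f_chir(v),      e_vu = f_bond(e^type) + f_dir(e^dir)
    h_v^(k) = MLP^(k)( h_v^(k-1) + sum_{u in N(v)} ( h_u^(k-1) + e_vu ) )
    h_G     = AGG({ h_v })                (mean / sum / gated attention)

A fully connected head maps `h_G` to class probabilities. Per task, a
hypernetwork reads the support set — each row `[embedding | predicted
probabilities | one-hot label]` — through a shared row encoder with
per-class mean pooling, and emits a Gaussian posterior over the flattened
head-weight delta:

    theta_i' ~ N( theta + u(S_i), exp(logvar(S_i)) )

Adapted heads are drawn by reparameterized sampling, and meta-training
minimizes, per episode of `Ns` tasks with class-balanced `2K`-molecule
support sets redrawn every episode,

    sum_i [ (1/P) sum_p CE(query_i; theta'_{i,p}) + gamma * KL(q_i || N(0, I)) ]

with one Adam step per episode on encoder, head and hypernetwork jointly.
A first-order MAML baseline and a no-adaptation baseline are included.
Evaluation draws a balanced K-shot support per meta-test task, averages the
probabilities of `P_eval` sampled heads on all remaining molecules, and
reports AUROC / PR-AUC / MCC as mean ± sd across tasks and repeats.

The methods vignette (`vignettes/bayesian-hypernetwork-metalearning.Rmd`)
documents the assumptions, the tunable parameters, the synthetic-data
design, and all numerical choices.

## Worked example

A synthetic benchmark pool with hidden structural motifs driving the
labels, a short meta-training run, and few-shot evaluation on held-out
tasks:

```r
library(molfewshot)

spec  <- synth_spec(n_tasks = 12, molecules_per_task = 100,
                    motif_library_size = 5, label_noise = 0.05, seed = 7)
pool  <- generate_pool(spec)
graphs <- attr(pool$matrix, "graphs")
tasks <- split_tasks(pool$matrix, "last_n", n = 3)   # 9 train / 3 test

cfg <- meta_config(K = 10, epochs = 30, seed = 7)
fit <- meta_train(tasks, graphs, cfg)                # d = 64, 3 GIN layers

set.seed(7)
res <- evaluate(fit$weights, fit$hyp, tasks, graphs, cfg,
                shots = 10, repeats = 4)
res$aggregate
```

```
  metric      mean         sd n_cells
1  auroc 0.8437742 0.04211763      12
2    mcc 0.5379685 0.13657760      12
3 pr_auc 0.7068119 0.13790046      12
```

Each row pools the 3 meta-test tasks × 4 independent 10-shot adaptations.
AUROC 0.84 means that after adapting to 10 labeled molecules per class, a
randomly chosen motif-positive molecule outranks a motif-negative one 84%
of the time — against ~0.5 for an untrained model; MCC scores the hard
classification at the 0.5 cutoff. This is a deliberately short run (30
epochs, ~3 minutes); the 100-epoch study configuration used by the
acceptance script reaches a 10-shot AUROC of 0.87 on its held-out tasks.
`fit$trace` holds the per-episode loss (`smooth_trace()` applies the
window-40 moving average used for monitoring).

A thin command-line wrapper covers the same pipeline
(`inst/cli/molfewshot.R`):

```sh
Rscript inst/cli/molfewshot.R simulate --out pool_dir --seed 7
Rscript inst/cli/molfewshot.R train    --data pool_dir/pool.csv --out run --seed 7
Rscript inst/cli/molfewshot.R eval     --data pool_dir/pool.csv --checkpoint run/checkpoint.rds --out run --shots 10
```

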