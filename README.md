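# blastpart

Performance-model-driven data partitioning for BLAST-style jobs on HPC
clusters.

A BLAST search takes a *database* of `D` sequences and a *query* of `Q`
sequences. Fanning the job out over a cluster means splitting the database
into `m` fragments and the query into `n` fragments and running all
`m × n` (fragment, fragment) pairs as independent sub-jobs; the whole job
finishes when the slowest sub-job does. blastpart is for people who run
large BLAST jobs through batch schedulers and want the split chosen by a
model instead of by habit. It:

* fits per-node-type runtime surfaces
  `T(D, Q) = c₁x² + c₂xy + c₃y² + c₄x + c₅y + c₆`
  (with `y = Q/10⁶` and `x = D/10⁶` or `log(D/10⁶)`) from profiling
  measurements by ordinary least squares;
* minimizes the cost `max_{i,j} T(Dᵢ, Qⱼ)` over candidate fragmentations
  `(m, ⌊P/m⌋)` for `P` nodes, with ceiling fragment sizes
  `Dᵢ = ⌈D/m⌉`, `Qⱼ = ⌈Q/n⌉` — for homogeneous clusters and, via
  power-proportional query quotas `W_k = s_k P_k`, for heterogeneous ones;
* materializes the chosen plan: streams the FASTA inputs into
  record-count fragments (byte-faithful, constant memory) and emits job
  manifests (shell / Grid Engine array / JSON) in which every command
  carries `-dbseqnum <D>` — the *original* database count, so E-values
  stay correct under database segmentation;
* parses Unix `time`, gprof flat profiles, and stopwatch logs into
  measurement tables, and generates synthetic grids, FASTA files, and
  profiler fixtures so everything runs offline.

A fitted reference coefficient set for the five core BLASTN functions,
per-node-type scaling factors, and multithreading speed-up tables ship
with the package.

## Worked example

```r
library(blastpart)

model <- reference_model("V", query_set = NULL)   # shipped five-surface model
job   <- job_spec(523449, 73102023)               # D and Q in sequences

solve_homogeneous(job, 4096, model)
#> <split_candidate> m=3 n=1365 (4095 nodes, 1 idle)  fragments (174,483, 53,555)  predicted 91.23 s

cluster <- list(node_type_profile("II", 2048, 0.3642),
                node_type_profile("V",  2048, 0.6358))
plan <- solve_heterogeneous(job, cluster,
  list(II = reference_model("II", query_set = NULL), V = model))
plan
#> <partition_plan> D=523,449, Q=73,102,023, 1 thread(s), cost 118.3 s
#>  node_type count  share per_node_quota m   n idle_nodes database_fragment
#>         II  2048 0.3642          13000 4 512          0            130863
#>          V  2048 0.6358          22695 3 682          2            174483
#>  query_fragment predicted_seconds
#>           52000          92.27839
#>           68150         118.27917
```

Reading the homogeneous result: of all ways to place `m × n ≤ 4096`
sub-jobs, cutting the database in 3 and the query in 1365 gives the
cheapest worst sub-job (each node searches 174,483 database sequences
against 53,555 query reads, predicted 91.2 s); one node idles. In the
heterogeneous plan, the slower Type II half of the cluster receives 36.42%
of the query (13,000 reads per node, rounded up to whole sequences) and
the faster Type V half 63.58% (22,695 per node); each half then solves its
own homogeneous sub-problem, and the plan's cost is the slower of the two
predictions.

From a shell, the same pipeline is available as subcommands (`fit`,
`predict`, `plan`, `split`, `manifest`, `parse-prof`, `synth`):

```sh
bp=$(Rscript -e 'cat(system.file("scripts", "blastpart", package = "blastpart"))')
"$bp" split --fasta query.fasta --parts 1365 --out-dir frags/
"$bp" plan --database-size 523449 --query-size 73102023 \
      --nodes 4096 --model model.json --out plan.json
```

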