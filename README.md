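# epimem

Hierarchical active-inference simulation of episodic memory.

`epimem` is for computational neuroscientists and computational-psychiatry
researchers who want a runnable, fully inspectable model of what it means to
*remember and recount* an episode — and of the distinct ways that process
can fail. A synthetic agent walks a Y-junction task (one path leads home,
the other is flooded; a signpost reveals which), is then asked a question
about what it did, and answers by *reconstructing* the episode: the walk is
replayed in its beliefs from a compressed slow-level description, and the
answer sentence is generated from the same description. Four precision
lesions — failure to encode, to retrieve, to attenuate, to retain — each
produce a recognizably different amnestic phenotype from a single healthy
model.

## The model in brief

Two coupled levels of discrete (categorical) state inference:

* **Fast (within-epoch).** Hidden factors (location, spatial context, a
  syntax chain, semantic answer slots) generate four modalities (vision,
  feedback, heard words, spoken words) over a 10-step horizon. For each
  candidate policy π, state posteriors come from **exact forward–backward
  smoothing** on the joint chain. Policies are scored by expected free
  energy,

      G(π) = Σ_τ Σ_m  KL[ Q(o_τ | π) || σ(C) ]  +  E_Q(s_τ|π) H[ P(o_τ | s_τ) ]
             (risk)                                (ambiguity)

  and selected through `q(π) = softmax(ln E − γ G)`; the risk term against
  *normalized* preferences carries the epistemic drive that sends the agent
  back to check the signpost before committing to a path.

* **Slow (across epochs).** A joint belief over narrative stage
  (walk → listen → answer) and time-invariant episode content (first move,
  second move, context, query topic). Link tables predict fast initial
  states and the fast policy prior from slow states (descending messages);
  end-of-epoch fast posteriors return as soft evidence (ascending
  messages); slow transitions carry content across epochs.

* **Precision is the lesion surface.** Every pathway carries an exponent ζ
  (`apply_precision(d, ζ) = normalize(d^ζ)`; ζ = 1 intact, ζ = 0 uniform).
  Syntax-conditioned attenuation flattens the visual likelihood during
  speech, which is what lets recollection ignore current sensation.

## Worked example

```r
library(epimem)

res <- run_condition("healthy")
res$summary
#> <epimem_phenotype> healthy
#>   replay fidelity: 1.000 | context recovery step: 1 | QA match: TRUE
#>   question: 'what was your first move'
#>   answer:   'I didnt-know the-route-home was on-the right so-I checked by-going back'
```

The healthy agent walks junction → signpost → right path (home), replays
that trajectory perfectly at the start of the two interview epochs
(fidelity 1.0), already knows the context at step 1 of the answer
(recovery step 1), and instantiates the answer template correctly for the
question that was actually asked.

All five conditions at the reference lesion severity 0.8:

```r
df <- summarize_all()
df[, c("condition", "replay_fidelity", "recovery_step", "qa_match")]
#>   condition replay_fidelity recovery_step qa_match
#> 1   healthy           1.000             1     TRUE
#> 2    encode           0.667             6    FALSE
#> 3  retrieve           1.000             1    FALSE
#> 4 attenuate           0.333             1     TRUE
#> 5    retain           1.000             6    FALSE
```

Reading the table: under the **encode** lesion the slow level never formed
precise beliefs, and the context is recovered only at step 6 of the answer
epoch — the moment the agent hears itself say "right". **Retrieve** leaves
replay intact but answers the unasked second-move question ("I knew … so I
found-it by going to-the-right"). **Attenuate** corrupts the replay
(fidelity ⅓: the un-suppressed junction view pins the replayed trajectory
to the crossroads) while the spoken answer stays healthy. **Retain** leaks
episode content between epochs until even the question is forgotten.

`run_condition(..., out_dir = "...")` exports belief rasters (CSV, rows =
states, columns = steps, 1 = full belief), a JSON summary and transcripts;
`plot = TRUE` adds a raster figure. A thin command-line front end ships in
`inst/cli/epimem.R`:

```sh
Rscript inst/cli/epimem.R run --condition attenuate --out out/
Rscript inst/cli/epimem.R suite --out out/
Rscript inst/cli/epimem.R validate-model inst/extdata/two_state_demo.yaml
```

User-defined generative models can be supplied in the same declarative
YAML/JSON schema as the built-in task (`load_model_spec()`,
`validate_model()`); see `inst/extdata/two_state_demo.yaml`.

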