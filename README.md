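# mitovo2

Automated analysis of **mitochondrial oxygen consumption (mitoVO₂)** from
cutaneous mitochondrial oxygen tension (mitoPO₂) recordings.

Skin-based protoporphyrin IX oximetry measures mitoPO₂ (mmHg) at 1 Hz.
Pressing the probe occludes the local microcirculation ("stop-flow"), so
mitoPO₂ falls at a rate set by mitochondrial consumption plus diffusive
oxygen influx from surrounding tissue. Historically, analysts selected
the start of each stop-flow decay by hand — slow, and a real source of
inter-observer variability. This package automates the analysis end to
end and is aimed at researchers working with such recordings:

1. **Detection** — a bidirectional LSTM labels every sample of a session
   trace as `start` / `measurement` / `na`, and a deterministic rule
   engine cleans the labels into valid measurement segments (start
   spacing, 20-mmHg validity bounds, start recentering, artifact
   rejection).
2. **Quantification** — each segment is fitted by bounded nonlinear
   least squares with the modified Michaelis–Menten oxygen disappearance
   model

   dP/dt = −V₀·P / (P₅₀ + P) + Z·(P₀ − P)

   integrated by Runge–Kutta; the steepest tangent of the fitted curve
   is the measurement's **V_max** (mmHg/s), and the mean V_max over a
   subject's valid measurements is the subject's mitoVO₂.

Because identical inputs produce identical labels and fits, repeat runs
agree exactly — removing the observer from the loop.

The package also provides a synthetic session generator with exact
ground truth (clinical recordings of this kind are generally not
shareable), start-point matching accuracies (acc₀/acc₁/acc₃/acc₅ within
a ±5-sample tolerance), and Bland–Altman agreement statistics including
extended limits of agreement for repeated measurements with unequal
replicate counts.

## Worked example

```r
library(mitovo2)

# simulate a small labeled cohort and train the start-point detector
cohort <- generate_cohort(cohort_config(n_subjects = 6, seed = 7))
model  <- train_segmenter(cohort, model_config(seed = 7))
print(model)

# analyze a new, unlabeled subject end to end
subject <- generate_subject(cohort_config(seed = 7), subject_seed = 4242,
                            subject_id = "demo")
labels  <- predict_labels(model, subject$trace)
cleaned <- apply_rules(labels, subject$trace)
result  <- fit_trace(subject$trace, cleaned$labels)

print(subject$trace)
cat("detected starts: ", paste(start_indices(cleaned$labels), collapse = ", "), "\n")
cat("true starts:     ", paste(sapply(subject$truth, `[[`, "start_index"), collapse = ", "), "\n")
print(result$fits[[1]])
valid <- sapply(subject$truth, `[[`, "valid")
cat(sprintf("subject mitoVO2: %.2f mmHg/s (ground truth: %.2f)\n", result$mitovo2,
            mean(sapply(subject$truth[valid], `[[`, "true_vmax"))))
rep <- match_starts(sort(sapply(subject$truth, `[[`, "start_index")),
                    start_indices(cleaned$labels))
print(rep)
```

prints (training takes ~30 s on one core):

```
biLSTM segmenter: 55 hidden units/direction, trained on 1036 windows (final loss 0.0873)
mitoPO2 trace 'demo': 1977 samples (1 Hz), range -3.8-84.9 mmHg
detected starts:  54, 295, 544, 758, 1014, 1261, 1499, 1725
true starts:      51, 294, 544, 758, 1012, 1261, 1495, 1726
segment fit (114 samples): Vmax = 7.295 mmHg/s, rmse = 1.599 mmHg, converged = TRUE
subject mitoVO2: 9.43 mmHg/s (ground truth: 10.22)
start matching: 8/8 reference points matched (acc0 0.375, acc1 0.625, acc3 0.875, acc5 1.000); 0 extra detections
```

All 8 stop-flow starts are found within the ±5-sample tolerance; each
segment's fit reports the decay's V_max and convergence; the subject's
mitoVO₂ is the mean V_max over converged fits. (A model trained on the
package's default 20-subject cohort detects most starts at offset 0 and
tracks ground-truth mitoVO₂ more closely; the 6-subject cohort above
keeps the example quick.)

`run_pipeline(input_dir, model, output_dir)` applies the same two steps
to every `*.trace.csv` in a directory and writes cleaned labels plus
per-subject `*.results.json`. A thin command-line front end with the
same verbs (`simulate`, `train`, `tune`, `detect`, `postprocess`, `fit`,
`run`, `validate`) is installed as `exec/mitovo2`.

## File formats

* `*.trace.csv` — header `sample_time_s,mitopo2_mmhg`; 1-Hz samples,
  UTF-8, `.` decimal. Vendor exports must be converted to this dialect.
* `*.labels.csv` — header `sample_time_s,label`; labels exactly
  `start`, `measurement`, `na` (case-sensitive).
* `*.results.json` — per subject: measurements with 0-based
  `start_index`/`end_index`, fitted `params` (v0, p50, p0, z),
  `vmax_mmhg_per_s`, `converged`, and the subject's
  `mitovo2_mmhg_per_s` (null when no measurement survives).

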