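# painvoice

Speech-based pain assessment for clinical and caregiving settings: detect
whether a short utterance was produced under pain, grade the pain intensity
(mild / moderate / severe), and recognize the thermal condition (cold vs.
warm water immersion) of a cold-pressor protocol — all from the audio alone.
The package is aimed at researchers who want a fully inspectable, dependency-
light reference implementation of a recurrent audio classifier, plus a
synthetic vocalization generator so every stage can be exercised and
validated without access to clinical recordings.

## Method

Each clip is standardized and classified by the following pipeline:

1. **Preprocessing** — mix to mono, band-limited resampling to
   fs = 8 kHz, then zero-pad or truncate to a fixed 3 s window:
   N = 3·fs = 24,000 samples.
2. **Log-Mel features** — Hann-windowed frames (N_FFT = 1024, hop
   H = 256, no centering), one-sided power spectrum |X_m[k]|²,
   a 64-filter triangular Mel filterbank on the HTK scale
   Mel(f) = 2595·log10(1 + f/700), and natural-log compression
   L = ln(S + ε), ε = 1e-9. A 24,000-sample clip yields a 90 × 64 matrix.
3. **Sequence classifier** — a stack of L = 3 bidirectional GRU layers
   (hidden size H = 64 per direction) over the frame sequence:

       z_t = σ(W_z x_t + U_z h_{t-1} + b_z)
       r_t = σ(W_r x_t + U_r h_{t-1} + b_r)
       h̃_t = tanh(W_h x_t + U_h (r_t ⊙ h_{t-1}) + b_h)
       h_t = (1 − z_t) ⊙ h_{t-1} + z_t ⊙ h̃_t

   with forward and backward hidden sequences concatenated per step,
   temporal mean pooling h̄ = (1/T) Σ_t h_t into one utterance embedding,
   dropout (p = 0.5), and a linear softmax head.
4. **Training** — class-balanced cross-entropy (inverse-frequency weights),
   Adam (lr 1e-4, coupled L2 weight decay 1e-5), batches of 8, at most 20
   epochs with early stopping after 3 epochs without test-accuracy
   improvement, best-epoch checkpointing, and speaker-independent
   (speaker-grouped) 80/20 splits. The forward pass, backpropagation
   through time, and Adam are implemented in plain R (BLAS-backed) and are
   verified against finite differences in the test suite.

Evaluation produces confusion matrices and per-class / macro / weighted
precision, recall, F1, and accuracy reports.

The synthetic corpus generator simulates vocalizations as a jittered
harmonic source with speaker-specific fundamental frequency (F0) and
spectral tilt; pain raises F0, energy, and jitter with intensity-dependent
effect sizes, and the thermal condition is marked by the amplitude-
modulation rate. All effect sizes are configurable, including down to zero
(a null corpus on which the classifier must not beat the majority rate).

## Worked example

```r
library(painvoice)

cfg    <- synth_config(n_speakers = 6, clips_per_speaker = 40, seed = 0)
corpus <- synth_corpus(cfg, file.path(tempdir(), "demo_corpus"))
res    <- train_task(corpus, "pain_binary", train_cfg = train_config(seed = 0))

print(res$cm)
print(res$report)
```

which trains for a few epochs (early stopping keeps epoch 4) and prints:

```
Confusion matrix (rows = true, columns = predicted)
          predicted
true       non-pain pain
  non-pain       20    0
  pain            1   19
Class          Precision  Recall  F1-Score
non-pain       0.9524  1.0000  0.9756
pain           1.0000  0.9500  0.9744
Macro Avg.     0.9762  0.9750  0.9750
Weighted Avg.  0.9762  0.9750  0.9750
Accuracy       0.9750
```

The test split contains only speakers the model never saw in training: of
40 held-out clips, one pain clip is missed and all non-pain clips are
recognized, i.e. the classifier has learned the F0/energy/jitter signature
of pain rather than speaker identity.

The same pipeline is available from a shell via the installed script:

```sh
painvoice synth --speakers 6 --clips 40 --seed 0 --out corpus/
painvoice train --corpus corpus/metadata.csv --task pain_binary --seed 0 --out run/
painvoice evaluate --corpus corpus/metadata.csv --checkpoint run/checkpoint.rds --task pain_binary --out eval/
painvoice ablate --corpus corpus/metadata.csv --seed 0 --out ablation/
```

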