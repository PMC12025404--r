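# whalemse

Detection and classification of Antarctic blue whale (*Balaenoptera
musculus intermedia*) vocalizations in continuous passive acoustic
recordings, for bioacousticians and ecological-monitoring pipelines that
need an automatic, threshold-free call detector for low-frequency
(typically 1 kHz) archive audio.

## Method

Blue whale Z calls (three stereotyped units between 18 and 27 Hz, 18–26 s
long) and D calls (22–106 Hz downsweeps of 1–4 s) are non-stationary, so
`whalemse` characterizes each audio window by its **multiscale sample
entropy** (MSE) profile rather than a spectral template. A window
$F_k$ of a band-passed (15–30 Hz Butterworth, zero phase), peak-normalized
recording is coarse-grained at scale $\tau$,

$$c_j(\tau) = \frac{1}{\tau} \sum_{i=(j-1)\tau+1}^{j\tau} w_i ,
\qquad 1 \le j \le \lfloor L/\tau \rfloor,$$

and its sample entropy

$$SE_k(\tau) = -\ln \frac{P_{m+1}}{P_m}$$

is the negative log conditional probability that two length-$m$ templates
matching within Chebyshev tolerance $r = 0.2\,\sigma$ still match when
extended by one sample ($m = 2$; $\sigma$ from the scale-1 window). Over
scales $\tau = 1,\dots,12$ this yields an $s \times 12$ feature matrix per
recording.

The features, log-transformed and standardized, go to a full-covariance
**Gaussian mixture model** fitted by EM. The mixture does triple duty:

* **feature reduction** — features are ranked by the mean posterior
  probability statistic $\mathrm{MPP}(j,f) = \frac1s \sum_i
  P(j \mid x_i)\,x_{if}$ and the top $\zeta = 4$ retained;
* **clustering** — maximum-a-posteriori component assignment;
* **classification** — held-out windows get the class (whale call vs
  other sound) of their maximum-likelihood component, components having
  been labeled by training-set majority.

PCA, dynamic mode decomposition and continuous-wavelet (energy /
spectral-centroid / entropy) extractors are included as baselines feeding
the identical mixture back-end, and a synthetic scene generator renders
annotated Z/D-call recordings at controlled in-band SNR so the whole
pipeline is testable without the multi-gigabyte Antarctic annotated
library.

## Worked example

```r
library(whalemse)

# 20 synthetic 26-s scenes at 10 dB in-band SNR: half contain a Z call
bench <- make_benchmark(n_scenes = 20, snr_db = 10, seed = 7)
bench$segments
#> segment_set: 20 windows of 26 s (26000 samples) at 1000 Hz
#>   labels: BmAntZ=10, noise=10

features <- extract_features(bench$segments, method = "mse")
report <- multi_run_summary(features, bench$labels, seeds = 1:5)
report
#> Detection performance across 5 trials (zeta = 4):
#>   accuracy   mean 100.00%  highest 100.00%  lowest 100.00%
#>   error rate mean 0.00%  highest 0.00%  lowest 0.00%
```

Each trial re-draws a stratified 70/30 train/test split and EM seed,
reduces the 12 entropy scales to the 4 most discriminative via the
mixture posteriors, refits on the training windows and classifies the
held-out ones; the report gives mean/highest/lowest accuracy and error
rate (which share a denominator and always sum to 1). At 10 dB in-band
SNR the entropy profiles of tonal calls and noise are essentially
disjoint, hence the perfect synthetic score — field recordings are
harder.

A command-line front end wraps the same functions
(`exec/whalemse simulate | extract | train | classify | evaluate`), with
flags mirroring `pipeline_config()` keys.

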