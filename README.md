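# eitsbt

Offline analysis of electrical impedance tomography (EIT) recordings made
around **spontaneous breathing trials (SBTs)** in prolonged ventilator
weaning. Patients in prolonged weaning can fail a T-piece trial abruptly —
through de-recruitment or ventilatory insufficiency — before blood gases or
bedside signs react. EIT movies of regional lung impedance offer a faster
window on those processes, but turning a raw 32 × 32 pixel movie into
interpretable numbers requires a chain of processing steps that this
package implements as a tested, reusable pipeline:

1. **Signal processing** — zero-phase Butterworth low-pass at 50 min⁻¹ to
   remove cardiac oscillations, computation of the global impedance curve,
   breath-cycle segmentation (end-expiration minima / end-inspiration
   maxima) with selection of ≥ 10 consecutive artifact-free breaths, and an
   EIT-derived respiratory rate.
2. **Ventilation indices** per session (t0 baseline on pressure support,
   t1 end of T-piece trial, t2 after return to pressure support):
   - **TIV** — tidal impedance variation, the breath-averaged
     end-inspiratory minus end-expiratory global impedance, referenced to
     the baseline session (t0 ≡ 100 %);
   - **ΔEELI** — change in end-expiratory lung impedance (mean of the
     global-curve minima), normalized by baseline TIV;
   - **IR / IR_adapt** — ventral-to-dorsal impedance ratio
     (ROI1 + ROI2)/(ROI3 + ROI4) over four horizontal bands, static
     (25 % of rows each) or adapted to each patient's ventilated extent;
   - **GI** — global inhomogeneity index,
     `GI = Σ_lung |DI_xy − median(DI_lung)| / Σ_lung DI_xy`,
     computed on the tidal image DI and reported ×100;
   - **spRVD** — regional ventilation delay under spontaneous breathing:
     per-pixel delay to reach 40/60/80 % of the pixel's tidal amplitude,
     as a percentage of the inspiration time, summarized across pixels
     (SD = heterogeneity; mean also emitted);
   - **RSBI_EIT** — respiratory rate over normalized TIV, the EIT analog
     of the rapid shallow breathing index.
3. **Cohort prediction** — deterioration labelling (tidal-volume drop
   ≥ 20 ml at t2 vs t0), ROC threshold sweep of baseline GI with
   Mann–Whitney AUC, operating points at arbitrary GI cutoffs, and
   median/IQR summary tables per session and outcome group.
4. **Synthetic data** — a two-ellipse thorax phantom with programmable
   amplitude maps, inspiratory delay fields, EELI trajectories, cardiac
   oscillation and noise, whose ground truth (TIV, GI, delay maps, EELI
   offsets, IR) is computed analytically from the parameters; and a
   virtual cohort generator with a binormal baseline-GI model whose
   theoretical AUC is known in closed form. Every pipeline stage is
   verified by parameter recovery against these phantoms.

## Worked example

A phantom session pair: baseline at 23.5 breaths·min⁻¹, then a simulated
T-piece session with tidal amplitude scaled to 72 %, an end-expiratory
baseline shift of −0.65 baseline tidal swings, and a rate of 26 min⁻¹,
both with 5 % amplitude noise:

```r
library(eitsbt)
support <- lung_ellipses(); m <- sum(support)
amp <- matrix(0, 32, 32); amp[support] <- 1
s0 <- phantom_spec(lung_amplitude_map = amp, respiratory_rate = 23.5,
                   duration = 36, noise_sd = 0.05, seed = 1L)
s1 <- phantom_spec(lung_amplitude_map = amp * 0.72, respiratory_rate = 26,
                   eeli_trajectory = -0.65 * sum(amp) / m, duration = 33,
                   noise_sd = 0.05, seed = 2L)
res <- analyze_patient(list(t0 = generate_phantom(s0, "t0", "demo")$frames,
                            t1 = generate_phantom(s1, "t1", "demo")$frames))
res[, c("session_label", "tiv_percent", "delta_eeli_percent", "rr",
        "rsbi_eit", "gi_reported", "ir", "sp_rvd_sd_40")]
#>   session_label tiv_percent delta_eeli_percent    rr rsbi_eit gi_reported
#> 1            t0      100.00               0.00 23.42    23.42      0.4439
#> 2            t1       71.79             -65.16 26.00    36.22      0.6627
#>       ir sp_rvd_sd_40
#> 1 0.9996        1.415
#> 2 1.0006        1.795
```

The pipeline recovers the programmed conditions: TIV falls to ~72 % of
baseline, the end-expiratory level drops by ~65 % of a baseline tidal
swing, the respiratory rate reads 23.4 → 26.0 min⁻¹, and RSBI_EIT rises
from 23.4 to 36.2 as breathing becomes faster and shallower. GI stays near
zero (the amplitude map is uniform) and IR near 1 (mirror-symmetric
lungs).

A cohort-level run, from virtual patients to a ROC curve:

```r
cohort  <- generate_cohort(cohort_spec(n_patients = 31, seed = 1L))
results <- analyze_cohort(cohort)
roc     <- roc_curve(results$patients$gi_baseline,
                     results$patients$deteriorated)
operating_point(roc, 41.5)
cohort_summary(results$sessions, results$patients,
               group_by = "deterioration")
```

The same chain is available from a shell via the thin wrapper in
`inst/cli/eitsbt` (subcommands `simulate`, `analyze`, `cohort`, `roc`,
`report`; flags `--config`, `--seed`, `--in`, `--out`, `--cutoff`).

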