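# File formats

All indices written to disk are 0-based (column names carry a `_0based`
suffix); in-memory R objects are 1-based.

## Matrices (vector modalities)
- `modality<i>.tsv`: cells x features, tab-separated, header row of feature
  names (`f1..fP` by default). A sparse MatrixMarket copy `modality<i>.mtx`
  is written alongside by `simulate`.

## Volumes (image modalities)
- One multi-page TIFF per nucleus, `nucleus%04d.tif`, one page per z-slice,
  32-bit float intensities in [0, 1].
- `nucleus%04d.mask.tif`: binary nuclear mask, same geometry.
- `nucleus%04d.spacing.txt`: voxel spacing in micrometres, `x<TAB>y<TAB>z`.

## Labels / pairing / anchors
- `labels<i>.tsv`: one column `label_0based`, one row per cell of modality i
  (in that modality's row order).
- `pairing.tsv`: one column `partner_row_0based`; row r of modality 1
  corresponds to row `partner_row` of modality 2.
- `anchors.tsv`: columns `i_0based`, `j_0based`; known corresponding rows of
  modalities 1 and 2.

## Radial profiles
- `profiles.tsv`: columns `nucleus`, `bin01..bin10`, `cluster`. Bins are
  intensity fractions at nuclear volume-fraction bins 0-10% .. 90-100%,
  read from the nuclear centre outward (bin01 is the central 0-10% of the
  nuclear volume, bin10 the peripheral shell).

## Training outputs
- `checkpoint.rds`: self-contained model container (architectures,
  parameters, normalization metadata, training log).
- `loss.tsv`: per-epoch loss terms (phase, domain, epoch, recon, kl,
  adv_gen, disc, classifier, anchor).
- `resolved-config.yaml`: the configuration the run actually used.
- `manifest.json`: command, package version, seed, config, input digests,
  output paths (written by every command).

## Evaluation reports
- `metrics.tsv`: metric, value, parameter, seed.
- `knn.tsv`: k, accuracy.
- `roc.tsv`: fpr, tpr points.
- `markers.tsv`: feature, mean_diff (log-fold-change on log-normalized
  data), t, p, p_adj, marker_group.
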