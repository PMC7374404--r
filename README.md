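# pupilloc

Coarse-to-fine pupil-centre localisation in low-resolution eye images, with
the evaluation metrics used for eye-centre benchmarks and a synthetic eye
renderer for fully reproducible testing.

`pupilloc` is aimed at people building gaze-estimation, eye-tracking or
facial-analysis pipelines who need a fast, dependency-light pupil localiser
that keeps working when eye frames are only a few dozen pixels wide, plus a
standard way to score any localiser against ground-truth annotations.

## Method

Within a cropped eye frame *E* (h<sub>e</sub> × w<sub>e</sub> greyscale), the
iris is a dark, approximately circular region on a lighter sclera with the
pupil as its darkest part. The localiser exploits this with two
one-dimensional template-matching cascades instead of a full 2D search:

1. **Validity gate.** A frame is processed only if a landmark backend found
   exactly one face and exactly two eyes; eye frames are the bounding boxes
   of the per-eye landmark points.
2. **Horizontal pass.** An iris template *K* is resized to the frame's full
   height and 0.4 · w<sub>e</sub> wide, the frame is padded left and right
   with a white rim (so rim positions stay matchable at extreme gaze), and
   *K* slides along x with a 1-px stride. Each overlap is scored with the
   normalised correlation coefficient

   S = Σ K′E′ / √(Σ K′² · Σ E′²),

   where K′ and E′ are the mean-centred template and patch.
3. **Dynamic threshold.** Positions scoring above the 90th percentile of the
   pass's score vector form the candidate set *M*; the mean of their
   x-coordinates gives R<sub>x</sub>, the iris rectangle's left edge.
4. **Vertical pass.** Within the iris rectangle (the kernel-width strip at
   R<sub>x</sub>), the kernel is resized to 0.4 of the strip height and
   slides along y the same way, giving R<sub>y</sub>.
5. **Centre.** C<sub>x</sub> = R<sub>x</sub> + ⌊w<sub>k</sub>/2⌋,
   C<sub>y</sub> = R<sub>y</sub> + ⌊h<sub>k</sub>/2⌋.

Evaluation metrics: per-frame **wec** and **bec** (worst/best per-eye
Euclidean error normalised by the interocular distance; wec ≤ 0.05 is
roughly "within the pupil diameter"), accuracy-vs-threshold curves, per-axis
MAE and R², and **S_ED** — the single-eye error as a percentage of the eye
frame's diagonal, which needs no second eye and is invariant to image scale
and resolution.

## Worked example

```r
library(pupilloc)

# render a mock face with two eyes and exact ground truth
mock <- render_face_mock(n_eyes = 2, seed = 1)
validate_frame(mock$n_faces, mock$n_eyes)$valid
#> [1] TRUE

eyes <- crop_eye_frames(mock$image, mock$landmarks)
left  <- locate_pupil(eyes$left)
right <- locate_pupil(eyes$right)
left
#> <pupil_estimate left: centre (38, 13), parent (80, 81)>
mock$truth
#>    side   x  y
#> 1  left  80 80
#> 2 right 185 79

wec(list(C_l = c(80, 80), C_r = c(185, 79)),
    list(C_l = left$centre_parent, C_r = right$centre_parent))
#> [1] 0.009523692
```

Both estimates land within a pixel of the true centres, so the worst-eye
error is under 1% of the interocular distance — well inside the 0.05
"within pupil diameter" band.

From a shell, the same pipeline is available as subcommands
(`exec/pupilloc synth | detect | eval | kernel`), e.g.
`exec/pupilloc synth --n 100 --seed 1 --out-dir data/` writes 100 synthetic
eye frames with a ground-truth `annotations.csv`. Users with the standard
eye-centre benchmark datasets on disk can reproduce published-style tables
by running `detect` on the images plus landmarks, then `eval` against the
dataset annotations (BioID-style `.eye` sidecars, generic CSV and JSON are
supported).

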