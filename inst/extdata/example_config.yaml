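# Example pipeline configuration for `runPipeline()` / `anisosim pipeline`.
# Paths are relative to where the pipeline is launched.

reference: atlas/reference.nii.gz        # common reference image (NIfTI)
rois:                                    # ROI id -> binary mask on the reference grid
  whole_brain: atlas/whole_brain.nii.gz
  cerebellum: atlas/cerebellum.nii.gz
frame: computed                          # "computed" (mid-sagittal + PCA) or a transform
                                         # JSON whose frame_U supplies U
cohort: cohort.csv                       # columns: subject,age,sex,image[,baseline]
# baseline_subjects: [sub001, sub002]    # alternative to a `baseline` column
registration:                            # optional overrides of registrationConfig()
  block_size: 5
  block_spacing: 2
  search_radius: 3
  keep_fraction: 0.75
  pyramid_levels: 3
  max_outer_iterations: 10
analyses: [fit_growth, compare_groups]
output: results/
seed: 0
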