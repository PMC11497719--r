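# Default synthetic-cohort configuration: per-stratum demographics and
# plasma marker moments (mean, sd in natural units) of the development
# memory-clinic cohort, with amyloid-positivity mixture fractions for the
# clinically defined (unstratified) dementia groups.
correlation: 0.3
groups:
  - name: SCD_abeta_neg
    group: SCD
    amyloid: negative
    n_subjects: 259
    age: {mean: 59, sd: 8}
    female_fraction: 0.42
    markers:
      abeta_ratio: {mean: 0.06, sd: 0.02}
      ptau181:     {mean: 1.44, sd: 0.88}
      gfap:        {mean: 66.0, sd: 36}
      nfl:         {mean: 11.4, sd: 6.7}
  - name: SCD_abeta_pos
    group: SCD
    amyloid: positive
    n_subjects: 64
    age: {mean: 68, sd: 6}
    female_fraction: 0.55
    markers:
      abeta_ratio: {mean: 0.05, sd: 0.01}
      ptau181:     {mean: 2.30, sd: 1.01}
      gfap:        {mean: 124, sd: 66}
      nfl:         {mean: 17.8, sd: 6.7}
  - name: MCI_abeta_neg
    group: MCI
    amyloid: negative
    n_subjects: 116
    age: {mean: 63, sd: 8}
    female_fraction: 0.20
    markers:
      abeta_ratio: {mean: 0.06, sd: 0.01}
      ptau181:     {mean: 1.53, sd: 0.79}
      gfap:        {mean: 73.6, sd: 34}
      nfl:         {mean: 15.6, sd: 13}
  - name: MCI_abeta_pos
    group: MCI
    amyloid: positive
    n_subjects: 167
    age: {mean: 67, sd: 7}
    female_fraction: 0.43
    markers:
      abeta_ratio: {mean: 0.05, sd: 0.01}
      ptau181:     {mean: 2.39, sd: 1.16}
      gfap:        {mean: 116, sd: 50}
      nfl:         {mean: 17.7, sd: 9.9}
  - name: AD_dementia
    group: AD_dementia
    abeta_positive_fraction: 1.0
    n_subjects: 320
    age: {mean: 64, sd: 8}
    female_fraction: 0.58
    markers:
      abeta_ratio: {mean: 0.05, sd: 0.01}
      ptau181:     {mean: 2.81, sd: 1.08}
      gfap:        {mean: 145, sd: 70}
      nfl:         {mean: 20.3, sd: 12}
  - name: FTD
    group: FTD
    abeta_positive_fraction: 0.17
    n_subjects: 162
    age: {mean: 63, sd: 9}
    female_fraction: 0.47
    markers:
      abeta_ratio: {mean: 0.06, sd: 0.01}
      ptau181:     {mean: 1.75, sd: 1.45}
      gfap:        {mean: 103, sd: 59}
      nfl:         {mean: 38.3, sd: 38}
  - name: DLB
    group: DLB
    abeta_positive_fraction: 0.49
    n_subjects: 111
    age: {mean: 69, sd: 7}
    female_fraction: 0.17
    markers:
      abeta_ratio: {mean: 0.05, sd: 0.01}
      ptau181:     {mean: 2.00, sd: 1.25}
      gfap:        {mean: 118, sd: 72}
      nfl:         {mean: 22.8, sd: 21}
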