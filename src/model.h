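#ifndef DIARYREACT_MODEL_H
#define DIARYREACT_MODEL_H

// Shared data view of the censored (skew-)normal two-level model.
// X is column-major (R layout), n x p; person is 0-based.
struct ModelData {
  const double* X;
  int n, p;
  const double* y;
  const int* censor;
  const int* person;
  int J;
  double lo, hi;
  bool skew;
  double beta_sd, sd_df, sd_scale, alpha_sd;
};

// theta = [beta (p), log sigma, log tau, alpha (if skew), eta (J)];
// returns the joint log posterior; fills grad (same length) if not null.
double model_lp_grad(const double* theta, double* grad, const ModelData& md);

double owen_t(double h, double a);

#endif
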