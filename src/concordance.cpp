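#include <Rcpp.h>
using namespace Rcpp;

// Pairwise concordance counts for right-censored data, with per-patient
// aggregates enabling an exact leave-one-out jackknife.
//
// A pair is comparable when the strictly earlier observed time is an event
// of the target cause; at tied times an event paired with a censored
// observation is comparable (the censored patient is known to have survived
// the event time), two tied events are not.  Concordant: the patient with
// the earlier event carries the higher score; tied scores count one half.
//
// [[Rcpp::export]]
List concordance_counts(NumericVector score, NumericVector time,
                        IntegerVector event) {
  const int n = score.size();
  if (time.size() != n || event.size() != n)
    stop("score, time and event must have equal length");
  NumericVector conc_i(n), disc_i(n), tied_i(n), comp_i(n);
  double C = 0.0, D = 0.0, T = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int a = -1, b = -1;  // a: earlier event, b: later/censored
      if (time[i] < time[j]) {
        if (event[i] == 1) { a = i; b = j; }
      } else if (time[j] < time[i]) {
        if (event[j] == 1) { a = j; b = i; }
      } else {  // tied observed times
        if (event[i] == 1 && event[j] == 0) { a = i; b = j; }
        else if (event[j] == 1 && event[i] == 0) { a = j; b = i; }
      }
      if (a < 0) continue;
      if (score[a] > score[b]) {
        C += 1.0; conc_i[a] += 1.0; conc_i[b] += 1.0;
      } else if (score[a] < score[b]) {
        D += 1.0; disc_i[a] += 1.0; disc_i[b] += 1.0;
      } else {
        T += 1.0; tied_i[a] += 1.0; tied_i[b] += 1.0;
      }
      comp_i[a] += 1.0; comp_i[b] += 1.0;
    }
  }
  return List::create(_["concordant"] = C, _["discordant"] = D,
                      _["tied_score"] = T,
                      _["conc_i"] = conc_i, _["disc_i"] = disc_i,
                      _["tied_i"] = tied_i, _["comp_i"] = comp_i);
}
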