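#include <Rcpp.h>
#include <queue>
#include <set>
#include <tuple>
#include <vector>

using namespace Rcpp;

// Finite-capacity multi-server queue with non-preemptive priorities and a
// piecewise-constant capacity schedule.  This is the single event-driven
// primitive behind every service station in the ED model (triage desks,
// shared visit rooms, dedicated red-area rooms, and the MIU).
//
// Semantics:
//  * `priority`: smaller value = more urgent; FIFO within a priority level
//    (ties broken by queue-entry time, then by input index).
//  * `cap_time`/`cap_level`: capacity is cap_level[k] on
//    [cap_time[k], cap_time[k+1]); cap_time[0] must be 0.
//  * Capacity step-downs are non-preemptive: rooms over the new level finish
//    their current patient and then retire.
//  * If `eject_when_closed` is true, whenever capacity drops to zero every
//    queued patient is ejected (time recorded); a patient arriving while
//    capacity is zero is ejected immediately.  This models the MIU closing
//    rule; ordinary units never eject.
//  * Events at equal times are processed as completions, then capacity
//    changes, then arrivals, so a patient arriving exactly at an opening
//    breakpoint can be seated at once.
//
// Returns per patient: service start time (`start`, NA if never started),
// integer `status` (0 = started service, 1 = ejected, 2 = still waiting at
// the horizon), and `eject_time` (NA unless status 1).  Only events strictly
// before `horizon` are processed.

// [[Rcpp::export]]
List queue_sim_cpp(NumericVector arrival, IntegerVector priority,
                   NumericVector service, NumericVector cap_time,
                   IntegerVector cap_level, double horizon,
                   bool eject_when_closed) {
  const int n = arrival.size();
  if (priority.size() != n || service.size() != n)
    stop("arrival, priority and service must have equal length");
  const int nc = cap_time.size();
  if (nc == 0 || cap_level.size() != nc) stop("invalid capacity schedule");
  if (cap_time[0] != 0) stop("capacity schedule must start at time 0");
  for (int k = 0; k < nc; ++k) {
    if (cap_level[k] < 0) stop("capacity levels must be nonnegative");
    if (k > 0 && cap_time[k] <= cap_time[k - 1])
      stop("capacity breakpoints must be strictly increasing");
  }
  for (int i = 0; i < n; ++i) {
    if (service[i] < 0) stop("service durations must be nonnegative");
    if (arrival[i] < 0) stop("arrival times must be nonnegative");
  }

  // arrival order (stable sort on time, then input index)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return arrival[a] < arrival[b]; });

  NumericVector start(n, NA_REAL), eject_time(n, NA_REAL);
  IntegerVector status(n, 2);  // default: censored / never started

  // waiting set ordered by (priority, entry time, index)
  typedef std::tuple<int, double, int> wkey;
  std::set<wkey> waiting;
  // completion events: min-heap on time
  std::priority_queue<double, std::vector<double>, std::greater<double> > done;

  int cur_cap = cap_level[0];
  int free_rooms = cur_cap;
  int retire_debt = 0;  // busy rooms that retire at their next completion
  int ai = 0;           // next arrival (in ord)
  int ci = 1;           // next capacity breakpoint

  auto try_start = [&](double now) {
    while (free_rooms > 0 && cur_cap > 0 && !waiting.empty()) {
      wkey head = *waiting.begin();
      waiting.erase(waiting.begin());
      int idx = std::get<2>(head);
      start[idx] = now;
      status[idx] = 0;
      --free_rooms;
      done.push(now + service[idx]);
    }
  };

  while (true) {
    // next event: completions first, then capacity changes, then arrivals
    double tD = done.empty() ? R_PosInf : done.top();
    double tC = (ci < nc) ? cap_time[ci] : R_PosInf;
    double tA = (ai < n) ? arrival[ord[ai]] : R_PosInf;
    double t = std::min(tD, std::min(tC, tA));
    if (!R_finite(t) || t >= horizon) break;

    if (tD <= tC && tD <= tA) {
      done.pop();
      if (retire_debt > 0)
        --retire_debt;
      else
        ++free_rooms;
      try_start(t);
    } else if (tC <= tA) {
      int lvl = cap_level[ci];
      ++ci;
      int delta = lvl - cur_cap;
      cur_cap = lvl;
      if (delta > 0) {
        int absorb = std::min(delta, retire_debt);
        retire_debt -= absorb;
        free_rooms += delta - absorb;
      } else if (delta < 0) {
        int need = -delta;
        int take = std::min(need, free_rooms);
        free_rooms -= take;
        retire_debt += need - take;  // rooms retiring at next completion
      }
      if (cur_cap == 0 && eject_when_closed) {
        for (std::set<wkey>::iterator it = waiting.begin();
             it != waiting.end(); ++it) {
          int idx = std::get<2>(*it);
          status[idx] = 1;
          eject_time[idx] = t;
        }
        waiting.clear();
      }
      try_start(t);
    } else {
      int idx = ord[ai];
      ++ai;
      if (cur_cap == 0 && eject_when_closed) {
        status[idx] = 1;
        eject_time[idx] = t;
      } else {
        waiting.insert(wkey(priority[idx], t, idx));
        try_start(t);
      }
    }
  }

  return List::create(_["start"] = start, _["status"] = status,
                      _["eject_time"] = eject_time);
}
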