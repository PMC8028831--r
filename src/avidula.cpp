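// Core simulator: virtual CPU, toroidal world, merit scheduler, chemostat
// resources, task classification, assay harnesses, dip statistic.
//
// All randomness flows through R's RNG (unif_rand) so that set.seed() in the
// R wrappers makes every simulation bit-reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Instruction set: 32 codes. a-z are the canonical heads instruction set,
// A-F are nop-X plus the messaging/rotation extension.
// ---------------------------------------------------------------------------

static const char* ALPHABET = "abcdefghijklmnopqrstuvwxyzABCDEF";

enum OpCode {
  OP_NOPA = 0, OP_NOPB, OP_NOPC, OP_IFNEQU, OP_IFLESS, OP_IFLABEL,
  OP_MOVHEAD, OP_JMPHEAD, OP_GETHEAD, OP_SETFLOW, OP_SHIFTR, OP_SHIFTL,
  OP_INC, OP_DEC, OP_PUSH, OP_POP, OP_SWAPSTK, OP_SWAP, OP_ADD, OP_SUB,
  OP_NAND, OP_HCOPY, OP_HALLOC, OP_HDIVIDE, OP_IO, OP_HSEARCH,
  OP_NOPX, OP_SENDMSG, OP_RETRMSG, OP_BCAST1, OP_ROTL, OP_ROTR
};

static const int GENOME_LEN = 120;
static const int MEM_LEN    = 240;
static const int N_TASKS    = 9;
static const double MERIT_FLOOR = 120.0;
static const int INBUF_CAP  = 3;
static const int MSGQ_CAP   = 32;
static const int STACK_CAP  = 16;
static const int LABEL_CAP  = 10;

// Table 2 reward weights, task order NOT NAND AND ORN OR ANDN NOR XOR EQU
static const double TASK_VALUE[N_TASKS] = {1, 1, 2, 2, 4, 4, 8, 8, 16};

static inline int codeIndex(char c) {
  const char* p = std::strchr(ALPHABET, c);
  if (p == nullptr) return OP_NOPX;  // corrupted code: treated as nop-X
  return (int)(p - ALPHABET);
}

static std::vector<uint8_t> decodeGenome(const std::string& s) {
  std::vector<uint8_t> g(s.size());
  for (size_t i = 0; i < s.size(); ++i) g[i] = (uint8_t)codeIndex(s[i]);
  return g;
}

static std::string encodeGenome(const std::vector<uint8_t>& g) {
  std::string s(g.size(), 'A');
  for (size_t i = 0; i < g.size(); ++i) s[i] = ALPHABET[g[i]];
  return s;
}

static inline int randInt(int n) {  // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// ---------------------------------------------------------------------------
// Task logic: 5-bit classification of an output against the input buffer.
// Returns a 9-bit mask in Table-2 order.
// ---------------------------------------------------------------------------

static int classifyOutput(uint32_t out, const std::deque<uint8_t>& buf) {
  int mask = 0;
  const uint32_t M = 31u;
  uint32_t o = out & M;
  size_t n = buf.size();
  for (size_t i = 0; i < n; ++i) {             // unary: NOT
    uint32_t A = buf[i];
    if ((~A & M) == o) { mask |= 1 << 0; break; }
  }
  for (size_t i = 0; i < n; ++i) {
    for (size_t j = 0; j < n; ++j) {
      if (i == j) continue;                    // ordered pairs, distinct slots
      uint32_t A = buf[i], B = buf[j];
      if ((~(A & B) & M) == o)          mask |= 1 << 1;  // NAND
      if (((A & B) & M) == o)           mask |= 1 << 2;  // AND
      if (((A | (~B & M)) & M) == o)    mask |= 1 << 3;  // ORN
      if (((A | B) & M) == o)           mask |= 1 << 4;  // OR
      if (((A & (~B & M)) & M) == o)    mask |= 1 << 5;  // ANDN
      if ((~(A | B) & M) == o)          mask |= 1 << 6;  // NOR
      if (((A ^ B) & M) == o)           mask |= 1 << 7;  // XOR
      if ((~(A ^ B) & M) == o)          mask |= 1 << 8;  // EQU
    }
  }
  return mask;
}

// ---------------------------------------------------------------------------
// Organism
// ---------------------------------------------------------------------------

struct Org {
  bool alive = false;
  std::vector<uint8_t> mem;      // 120, or 240 after h-alloc
  bool allocated = false;
  uint32_t reg[3] = {0, 0, 0};   // AX BX CX
  std::vector<uint32_t> stacks[2];
  int activeStack = 0;
  int heads[4] = {0, 0, 0, 0};   // IP READ WRITE FLOW
  std::deque<uint8_t> inbuf;     // most recent environmental inputs
  std::vector<uint8_t> copiedLabel;
  double merit = MERIT_FLOOR;
  double pendingBonus = 0.0;
  int facing = 0;
  std::deque<std::pair<uint32_t, uint32_t> > msgq;
  long taskCounts[N_TASKS] = {0};
  long gestation = 0;
  long age = 0;
  int gid = -1;                  // seeded-genotype id, -1 once diverged
  std::vector<uint8_t> genome;   // heritable sequence at birth

  void initFrom(const std::vector<uint8_t>& g, double m, int face) {
    alive = true;
    genome = g;
    mem = g;
    allocated = false;
    reg[0] = reg[1] = reg[2] = 0;
    stacks[0].clear(); stacks[1].clear();
    activeStack = 0;
    heads[0] = heads[1] = heads[2] = heads[3] = 0;
    inbuf.clear();
    copiedLabel.clear();
    merit = m;
    pendingBonus = 0.0;
    facing = face;
    msgq.clear();
    for (int t = 0; t < N_TASKS; ++t) taskCounts[t] = 0;
    gestation = 0;
    age = 0;
  }

  int ext() const { return (int)mem.size(); }

  void resetAfterDivide() {
    mem.resize(GENOME_LEN);
    allocated = false;
    reg[0] = reg[1] = reg[2] = 0;
    stacks[0].clear(); stacks[1].clear();
    activeStack = 0;
    heads[0] = heads[1] = heads[2] = heads[3] = 0;
    copiedLabel.clear();
    gestation = 0;
    // input buffer and message queue persist across divides
  }
};

// Effects emitted by one cycle, applied by the caller (world or harness).
struct CycleFx {
  bool divided = false;
  std::vector<uint8_t> offspring;
  bool sent = false, bcast = false;
  uint32_t msg1 = 0, msg2 = 0;
  int taskMask = 0;          // tasks matched by an output this cycle
  bool output = false;
  uint32_t outputVal = 0;
  bool copied = false;
  bool copyMutated = false;
};

// find first occurrence of the complement label scanning forward (with wrap)
// from position `from`; returns -1 when absent.
static int findComplement(const std::vector<uint8_t>& mem, int from,
                          const std::vector<uint8_t>& label) {
  int n = (int)mem.size();
  int L = (int)label.size();
  if (L == 0 || L > n) return -1;
  std::vector<uint8_t> comp(L);
  for (int k = 0; k < L; ++k) comp[k] = (label[k] + 1) % 3;
  for (int d = 0; d < n; ++d) {
    int p = (from + d) % n;
    bool ok = true;
    for (int k = 0; k < L; ++k) {
      if (mem[(p + k) % n] != comp[k]) { ok = false; break; }
    }
    if (ok) return p;
  }
  return -1;
}

// Execute one instruction of `o`.  copyMut is the per-copy substitution
// probability of h-copy (zero in the main evolutionary loop, where mutation
// is applied as a whole-genome pass on divide).
static void vmCycle(Org& o, double copyMut, CycleFx& fx) {
  int n = o.ext();
  int ip = o.heads[0] % n;
  int op = o.mem[ip];
  bool advance = true;
  int extraSkip = 0;

  // read one optional nop modifier after the instruction (consumed)
  auto nopArg = [&](int deflt) -> int {
    int nxt = (ip + 1) % n;
    int c = o.mem[nxt];
    if (c <= OP_NOPC) { ip = nxt; return c; }
    return deflt;
  };
  // read a full nop label following the instruction (consumed)
  auto readLabel = [&]() -> std::vector<uint8_t> {
    std::vector<uint8_t> lab;
    while ((int)lab.size() < LABEL_CAP) {
      int nxt = (ip + 1) % n;
      int c = o.mem[nxt];
      if (c > OP_NOPC) break;
      lab.push_back((uint8_t)c);
      ip = nxt;
    }
    return lab;
  };

  switch (op) {
  case OP_NOPA: case OP_NOPB: case OP_NOPC: case OP_NOPX:
  default:
    break;
  case OP_IFNEQU: {
    int r = nopArg(1), c = (r + 1) % 3;
    if (o.reg[r] == o.reg[c]) extraSkip = 1;
    break;
  }
  case OP_IFLESS: {
    int r = nopArg(1), c = (r + 1) % 3;
    if (!(o.reg[r] < o.reg[c])) extraSkip = 1;
    break;
  }
  case OP_IFLABEL: {
    std::vector<uint8_t> lab = readLabel();
    bool match = false;
    int L = (int)lab.size();
    if (L > 0 && (int)o.copiedLabel.size() >= L) {
      match = true;
      for (int k = 0; k < L; ++k) {
        uint8_t comp = (lab[k] + 1) % 3;
        if (o.copiedLabel[o.copiedLabel.size() - L + k] != comp) {
          match = false; break;
        }
      }
    }
    if (!match) extraSkip = 1;
    break;
  }
  case OP_MOVHEAD: {
    int h = nopArg(0);
    o.heads[h] = o.heads[3] % n;
    if (h == 0) { advance = false; o.heads[0] %= n; }
    break;
  }
  case OP_JMPHEAD: {
    int h = nopArg(0);
    if (h == 0) ip = (int)((ip + (long)(o.reg[2] % (uint32_t)n)) % n);
    else o.heads[h] = (int)((o.heads[h] + (long)(o.reg[2] % (uint32_t)n)) % n);
    break;
  }
  case OP_GETHEAD: {
    int h = nopArg(0);
    o.reg[2] = (uint32_t)(h == 0 ? ip : o.heads[h] % n);
    break;
  }
  case OP_SETFLOW: {
    int r = nopArg(2);
    o.heads[3] = (int)(o.reg[r] % (uint32_t)n);
    break;
  }
  case OP_SHIFTR: { int r = nopArg(1); o.reg[r] >>= 1; break; }
  case OP_SHIFTL: { int r = nopArg(1); o.reg[r] <<= 1; break; }
  case OP_INC:    { int r = nopArg(1); o.reg[r] += 1u; break; }
  case OP_DEC:    { int r = nopArg(1); o.reg[r] -= 1u; break; }
  case OP_PUSH: {
    int r = nopArg(1);
    std::vector<uint32_t>& st = o.stacks[o.activeStack];
    if ((int)st.size() >= STACK_CAP) st.erase(st.begin());
    st.push_back(o.reg[r]);
    break;
  }
  case OP_POP: {
    int r = nopArg(1);
    std::vector<uint32_t>& st = o.stacks[o.activeStack];
    if (st.empty()) o.reg[r] = 0u;
    else { o.reg[r] = st.back(); st.pop_back(); }
    break;
  }
  case OP_SWAPSTK: o.activeStack ^= 1; break;
  case OP_SWAP: {
    int r = nopArg(1), c = (r + 1) % 3;
    std::swap(o.reg[r], o.reg[c]);
    break;
  }
  case OP_ADD:  { int r = nopArg(1); o.reg[r] = o.reg[1] + o.reg[2]; break; }
  case OP_SUB:  { int r = nopArg(1); o.reg[r] = o.reg[1] - o.reg[2]; break; }
  case OP_NAND: { int r = nopArg(1); o.reg[r] = ~(o.reg[1] & o.reg[2]); break; }
  case OP_HCOPY: {
    if (!o.allocated) break;
    uint8_t c = o.mem[o.heads[1] % n];
    bool mut = (copyMut > 0.0 && unif_rand() < copyMut);
    if (mut) { c = (uint8_t)randInt(32); fx.copyMutated = true; }
    int w = o.heads[2] % n;
    o.mem[w] = c;
    o.heads[1] = (o.heads[1] + 1) % n;
    o.heads[2] = (w + 1) % n;
    if (c <= OP_NOPC) {
      if ((int)o.copiedLabel.size() >= LABEL_CAP)
        o.copiedLabel.erase(o.copiedLabel.begin());
      o.copiedLabel.push_back(c);
    } else {
      o.copiedLabel.clear();
    }
    fx.copied = true;
    break;
  }
  case OP_HALLOC: {
    if (!o.allocated) {
      o.mem.resize(MEM_LEN, (uint8_t)OP_NOPX);
      o.allocated = true;
      o.heads[2] = GENOME_LEN;  // write head at start of offspring region
    }
    break;
  }
  case OP_HDIVIDE: {
    if (!o.allocated) break;  // malformed replicator: no-op
    fx.divided = true;
    fx.offspring.assign(o.mem.begin() + GENOME_LEN, o.mem.end());
    o.resetAfterDivide();
    advance = false;
    break;
  }
  case OP_IO: {
    int r = nopArg(1);
    fx.output = true;
    fx.outputVal = o.reg[r];
    fx.taskMask = classifyOutput(o.reg[r], o.inbuf);
    uint32_t in = (uint32_t)randInt(32);
    o.reg[r] = in;
    if ((int)o.inbuf.size() >= INBUF_CAP) o.inbuf.pop_front();
    o.inbuf.push_back((uint8_t)in);
    break;
  }
  case OP_HSEARCH: {
    int self = ip;
    std::vector<uint8_t> lab = readLabel();
    if (lab.empty()) {
      o.heads[3] = (self + 1) % n;
      o.reg[1] = 0u; o.reg[2] = 0u;
    } else {
      int pos = findComplement(o.mem, (ip + 1) % n, lab);
      if (pos < 0) {
        o.heads[3] = self;  // no-match convention
      } else {
        o.heads[3] = pos;
        o.reg[1] = (uint32_t)(((pos - ip - 1) % n + n) % n);
        o.reg[2] = (uint32_t)lab.size();
      }
    }
    break;
  }
  case OP_SENDMSG:
    fx.sent = true; fx.msg1 = o.reg[1]; fx.msg2 = o.reg[2];
    break;
  case OP_RETRMSG:
    if (!o.msgq.empty()) {
      o.reg[1] = o.msgq.front().first;
      o.reg[2] = o.msgq.front().second;
      o.msgq.pop_front();
    }
    break;
  case OP_BCAST1:
    fx.bcast = true; fx.msg1 = o.reg[1]; fx.msg2 = o.reg[2];
    break;
  case OP_ROTL: o.facing = (o.facing + 7) % 8; break;
  case OP_ROTR: o.facing = (o.facing + 1) % 8; break;
  }

  if (advance) o.heads[0] = (ip + 1 + extraSkip) % o.ext();
  o.gestation += 1;
  o.age += 1;
}

// ---------------------------------------------------------------------------
// World
// ---------------------------------------------------------------------------

struct PendingMsg { int target; uint32_t v1, v2; };

// Largest-remainder merit-proportional allocation of `total` cycles.
static std::vector<long> allocateCycles(const std::vector<double>& merits,
                                        long total) {
  int n = (int)merits.size();
  std::vector<long> quota(n, 0);
  if (n == 0) return quota;
  double msum = 0;
  for (int i = 0; i < n; ++i) msum += merits[i];
  if (msum <= 0) {  // degenerate: equal split
    for (int i = 0; i < n; ++i) quota[i] = total / n;
    for (long r = 0; r < total % n; ++r) quota[r] += 1;
    return quota;
  }
  std::vector<std::pair<double, int> > rem(n);
  long assigned = 0;
  for (int i = 0; i < n; ++i) {
    double share = total * merits[i] / msum;
    long q = (long)share;
    quota[i] = q;
    assigned += q;
    rem[i] = std::make_pair(-(share - q), i);  // ties: lower index first
  }
  std::sort(rem.begin(), rem.end());
  for (long r = 0; r < total - assigned; ++r) quota[rem[r % n].second] += 1;
  return quota;
}

// [[Rcpp::export]]
NumericVector cpp_allocate_cycles(NumericVector merits, double total) {
  std::vector<double> m(merits.begin(), merits.end());
  std::vector<long> q = allocateCycles(m, (long)total);
  NumericVector out(q.size());
  for (size_t i = 0; i < q.size(); ++i) out[i] = (double)q[i];
  return out;
}

struct World {
  int W, H, N;
  std::vector<Org> cells;
  std::vector<int> nbr;           // 8 per cell: N NE E SE S SW W NW
  std::vector<double> res;        // N_TASKS x N, column-major by cell
  double Rstar, uptake, cmax, delta, diffusion;
  double mutRate;
  std::vector<PendingMsg> pending;
  long births = 0, deaths = 0, mutEvents = 0, mutDraws = 0;
  std::vector<std::vector<long> > gidTasks;  // per seeded genotype

  World(int w, int h) : W(w), H(h), N(w * h), cells(N) {
    nbr.resize(8 * N);
    static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
    static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c)
        for (int d = 0; d < 8; ++d) {
          int rr = (r + dr[d] + H) % H, cc = (c + dc[d] + W) % W;
          nbr[8 * (r * W + c) + d] = rr * W + cc;
        }
  }

  int popSize() const {
    int k = 0;
    for (int i = 0; i < N; ++i) if (cells[i].alive) ++k;
    return k;
  }

  void initResources() { res.assign((size_t)N_TASKS * N, Rstar); }

  void rewardTasks(Org& o, int cell, int mask) {
    for (int t = 0; t < N_TASKS; ++t) {
      if (!(mask & (1 << t))) continue;
      o.taskCounts[t] += 1;
      if (o.gid >= 0) gidTasks[o.gid][t] += 1;
      double& lvl = res[(size_t)t * N + cell];
      double consumed = std::min(uptake * lvl, cmax);
      if (consumed < 0) consumed = 0;
      lvl -= consumed;
      o.pendingBonus += TASK_VALUE[t] * consumed;
    }
  }

  std::vector<uint8_t> mutate(const std::vector<uint8_t>& g) {
    std::vector<uint8_t> out = g;
    mutDraws += (long)g.size();
    if (mutRate > 0.0) {
      for (size_t i = 0; i < out.size(); ++i) {
        if (unif_rand() < mutRate) {
          out[i] = (uint8_t)randInt(32);
          ++mutEvents;
        }
      }
    }
    return out;
  }

  // returns index of the newborn's cell
  int placeOffspring(int parentCell, const std::vector<uint8_t>& genome) {
    Org& par = cells[parentCell];
    double newMerit = MERIT_FLOOR * (1.0 + par.pendingBonus);
    if (newMerit < MERIT_FLOOR) newMerit = MERIT_FLOOR;
    par.merit = newMerit;
    par.pendingBonus = 0.0;
    std::vector<uint8_t> child = mutate(genome);
    int target = nbr[8 * parentCell + par.facing];
    Org& tc = cells[target];
    if (tc.alive) ++deaths;
    int gid = (par.gid >= 0 && child == par.genome) ? par.gid : -1;
    tc.initFrom(child, newMerit, randInt(8));
    tc.gid = gid;
    ++births;
    return target;
  }

  void runCycles(int cell, long k, long& executed) {
    for (long c = 0; c < k; ++c) {
      Org& o = cells[cell];     // re-fetch: occupant may have been replaced
      if (!o.alive) break;
      CycleFx fx;
      vmCycle(o, 0.0, fx);
      ++executed;
      if (fx.output) rewardTasks(o, cell, fx.taskMask);
      if (fx.sent)
        pending.push_back(PendingMsg{nbr[8 * cell + o.facing], fx.msg1, fx.msg2});
      if (fx.bcast)
        for (int d = 0; d < 8; ++d)
          pending.push_back(PendingMsg{nbr[8 * cell + d], fx.msg1, fx.msg2});
      if (fx.divided) placeOffspring(cell, fx.offspring);
    }
  }

  void deliverMessages() {
    for (size_t i = 0; i < pending.size(); ++i) {
      Org& t = cells[pending[i].target];
      if (!t.alive) continue;  // messages into empty cells are discarded
      if ((int)t.msgq.size() >= MSGQ_CAP) t.msgq.pop_front();
      t.msgq.push_back(std::make_pair(pending[i].v1, pending[i].v2));
    }
    pending.clear();
  }

  void chemostatStep() {
    for (int t = 0; t < N_TASKS; ++t) {
      double* lv = &res[(size_t)t * N];
      for (int i = 0; i < N; ++i) lv[i] += delta * (Rstar - lv[i]);
      if (diffusion > 0) {
        std::vector<double> old(lv, lv + N);
        for (int i = 0; i < N; ++i) {
          double m = 0;
          const int* nb = &nbr[8 * i];
          for (int d = 0; d < 8; ++d) m += old[nb[d]];
          lv[i] = (1.0 - diffusion) * old[i] + diffusion * (m / 8.0);
        }
      }
    }
  }

  // One update: merit-proportional largest-remainder allocation of
  // 30 x N cycles; the quota belongs to the cell, so a replacing offspring
  // inherits its victim's unspent cycles and total execution is exact.
  long updateStep(int cyclesPerOrg, long& executedOut) {
    std::vector<int> aliveIdx;
    aliveIdx.reserve(N);
    double meritSum = 0;
    for (int i = 0; i < N; ++i)
      if (cells[i].alive) { aliveIdx.push_back(i); meritSum += cells[i].merit; }
    int n = (int)aliveIdx.size();
    if (n == 0) return 0;
    (void)meritSum;
    long total = (long)cyclesPerOrg * n;
    std::vector<double> merits(n);
    for (int k = 0; k < n; ++k) merits[k] = cells[aliveIdx[k]].merit;
    std::vector<long> alloc = allocateCycles(merits, total);
    std::vector<long> quota(N, 0);
    for (int k = 0; k < n; ++k) quota[aliveIdx[k]] = alloc[k];

    long executed = 0;
    for (int k = 0; k < n; ++k) {
      int i = aliveIdx[k];
      long q = quota[i];
      quota[i] = 0;
      runCycles(i, q, executed);
    }
    // drain quotas transferred to cells already visited this update
    bool more = true;
    while (more) {
      more = false;
      for (int i = 0; i < N; ++i) {
        if (quota[i] > 0 && cells[i].alive) {
          long q = quota[i];
          quota[i] = 0;
          runCycles(i, q, executed);
          more = true;
        }
      }
    }
    deliverMessages();
    chemostatStep();
    executedOut = executed;
    return n;
  }
};

// ---------------------------------------------------------------------------
// Exported: task classification
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_classify_output(int output, IntegerVector buffer) {
  std::deque<uint8_t> buf;
  for (int i = 0; i < buffer.size(); ++i) buf.push_back((uint8_t)(buffer[i] & 31));
  int mask = classifyOutput((uint32_t)output, buf);
  std::vector<int> hits;
  for (int t = 0; t < N_TASKS; ++t) if (mask & (1 << t)) hits.push_back(t + 1);
  return wrap(hits);
}

// [[Rcpp::export]]
std::string cpp_alphabet() { return std::string(ALPHABET); }

// [[Rcpp::export]]
int cpp_find_label(std::string memory, int from, std::string label) {
  std::vector<uint8_t> mem = decodeGenome(memory);
  std::vector<uint8_t> lab = decodeGenome(label);
  return findComplement(mem, from, lab);
}

// ---------------------------------------------------------------------------
// Exported: single-organism harness (isolation assay, phenotype profile,
// viability, gestation tracing).  Saturating-resource reward: each task
// performance consumes min(uptake * level, cmax) of a non-depleting level.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_isolation_run(std::string genome, int budget, double copyMut,
                       double resourceLevel, double uptake, double cmax,
                       bool stopAtDivide, bool trace) {
  Org o;
  o.initFrom(decodeGenome(genome), MERIT_FLOOR, 0);
  double consumedPer = std::min(uptake * resourceLevel, cmax);
  if (consumedPer < 0) consumedPer = 0;
  long gest = -1;
  long copies = 0, copyMutEvents = 0;
  bool divided = false;
  std::vector<double> outputs;
  std::string offspring;
  double merit = NA_REAL;
  std::vector<long> taskCounts(N_TASKS, 0);
  std::vector<int> trCycle, trIp, trOp, trEvent;  // event codes: see R layer

  for (long cyc = 1; cyc <= budget; ++cyc) {
    int ipAt = o.heads[0];
    int opAt = o.mem[ipAt % o.ext()];
    CycleFx fx;
    vmCycle(o, copyMut, fx);
    int ev = 0;
    if (fx.output) {
      ev = 1;
      outputs.push_back((double)fx.outputVal);
      for (int t = 0; t < N_TASKS; ++t) {
        if (fx.taskMask & (1 << t)) {
          taskCounts[t] += 1;
          o.pendingBonus += TASK_VALUE[t] * consumedPer;
        }
      }
    }
    if (fx.copied) { ev = 2; ++copies; if (fx.copyMutated) ++copyMutEvents; }
    if (fx.divided) {
      ev = 3;
      if (!divided) {
        divided = true;
        gest = cyc;
        offspring = encodeGenome(fx.offspring);
        merit = MERIT_FLOOR * (1.0 + o.pendingBonus);
        o.merit = merit;
        o.pendingBonus = 0.0;
      }
    }
    if (trace) {
      trCycle.push_back((int)cyc);
      trIp.push_back(ipAt);
      trOp.push_back(opAt);
      trEvent.push_back(ev);
    }
    if (divided && stopAtDivide) break;
  }

  List out = List::create(
    _["divided"] = divided,
    _["gestation"] = divided ? (double)gest : R_PosInf,
    _["merit"] = divided ? merit : MERIT_FLOOR,
    _["offspring"] = offspring,
    _["taskCounts"] = wrap(taskCounts),
    _["copies"] = (double)copies,
    _["copyMutEvents"] = (double)copyMutEvents,
    _["outputs"] = wrap(outputs),
    _["registers"] = NumericVector::create((double)o.reg[0], (double)o.reg[1],
                                           (double)o.reg[2]));
  if (trace) {
    out["trace"] = DataFrame::create(
      _["cycle"] = trCycle, _["ip"] = trIp,
      _["op"] = trOp, _["event"] = trEvent);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exported: world run
// ---------------------------------------------------------------------------

static List snapshotWorld(const World& w, int update) {
  std::vector<int> cell, facing;
  std::vector<double> merit;
  std::vector<std::string> genome;
  std::vector<long> counts;
  for (int i = 0; i < w.N; ++i) {
    if (!w.cells[i].alive) continue;
    cell.push_back(i);
    facing.push_back(w.cells[i].facing);
    merit.push_back(w.cells[i].merit);
    genome.push_back(encodeGenome(w.cells[i].genome));
    for (int t = 0; t < N_TASKS; ++t) counts.push_back(w.cells[i].taskCounts[t]);
  }
  IntegerMatrix tc((int)cell.size(), N_TASKS);
  for (int i = 0; i < (int)cell.size(); ++i)
    for (int t = 0; t < N_TASKS; ++t) tc(i, t) = (int)counts[(size_t)i * N_TASKS + t];
  return List::create(
    _["update"] = update, _["cell"] = wrap(cell), _["genome"] = wrap(genome),
    _["merit"] = wrap(merit), _["facing"] = wrap(facing), _["taskCounts"] = tc);
}

// [[Rcpp::export]]
List cpp_run_world(int width, int height, IntegerVector initCell,
                   CharacterVector initGenome, IntegerVector initFacing,
                   NumericVector initMerit, int updates, double mutRate,
                   double Rstar, double uptake, double cmax, double delta,
                   double diffusion, int cyclesPerOrg, int snapshotEvery) {
  World w(width, height);
  w.Rstar = Rstar; w.uptake = uptake; w.cmax = cmax;
  w.delta = delta; w.diffusion = diffusion; w.mutRate = mutRate;
  w.initResources();
  int nInit = initCell.size();
  w.gidTasks.assign(nInit, std::vector<long>(N_TASKS, 0));
  for (int k = 0; k < nInit; ++k) {
    int c = initCell[k];
    if (c < 0 || c >= w.N) stop("initial cell index out of range");
    int face = initFacing[k] >= 0 ? initFacing[k] % 8 : randInt(8);
    w.cells[c].initFrom(decodeGenome(as<std::string>(initGenome[k])),
                        initMerit[k], face);
    w.cells[c].gid = k;
  }

  std::vector<int> logUpdate, logPop;
  std::vector<double> logBirths, logDeaths, logMeanMerit, logCycles;
  List snaps;
  bool extinct = false;

  for (int u = 1; u <= updates; ++u) {
    long b0 = w.births, d0 = w.deaths;
    long executed = 0;
    int n = (int)w.updateStep(cyclesPerOrg, executed);
    if (n == 0) { extinct = true; break; }
    double msum = 0; int m = 0;
    for (int i = 0; i < w.N; ++i)
      if (w.cells[i].alive) { msum += w.cells[i].merit; ++m; }
    logUpdate.push_back(u);
    logBirths.push_back((double)(w.births - b0));
    logDeaths.push_back((double)(w.deaths - d0));
    logPop.push_back(n);  // scheduler census: organisms at update start
    logMeanMerit.push_back(m > 0 ? msum / m : NA_REAL);
    logCycles.push_back((double)executed);
    if (snapshotEvery > 0 && (u % snapshotEvery) == 0 && u < updates)
      snaps.push_back(snapshotWorld(w, u));
    if ((u & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix gidTc(nInit, N_TASKS);
  for (int k = 0; k < nInit; ++k)
    for (int t = 0; t < N_TASKS; ++t) gidTc(k, t) = (int)w.gidTasks[k][t];

  return List::create(
    _["log"] = DataFrame::create(
      _["update"] = logUpdate, _["births"] = logBirths,
      _["deaths"] = logDeaths, _["population"] = logPop,
      _["meanMerit"] = logMeanMerit, _["cycles"] = logCycles),
    _["final"] = snapshotWorld(w, updates),
    _["snapshots"] = snaps,
    _["extinct"] = extinct,
    _["mutEvents"] = (double)w.mutEvents,
    _["mutDraws"] = (double)w.mutDraws,
    _["genotypeTaskTotals"] = gidTc);
}

// [[Rcpp::export]]
IntegerVector cpp_neighbors(int width, int height, int cell) {
  World w(width, height);
  IntegerVector out(8);
  for (int d = 0; d < 8; ++d) out[d] = w.nbr[8 * cell + d];
  return out;
}

// ---------------------------------------------------------------------------
// Hartigan dip statistic.
//
// Uses the convex-minorant / concave-majorant characterization: for a
// candidate mode at data point m, the best convex fit left of m deviates
// from the ecdf by half the largest gap between the upper step corners
// (i/n) and the greatest convex minorant of the lower corners ((i-1)/n);
// mirrored on the right with the least concave majorant.  The dip is half
// the minimum over m of the larger one-sided gap.  An atom is allowed at
// the mode, so the jump at m itself is excluded on both sides.
// ---------------------------------------------------------------------------

// gaps[m] = max over interior points i < m of the vertical distance from the
// upper step corner (x_i, (i+1)/n) down to the greatest convex minorant of
// the lower corners {(x_j, j/n) : j <= m}.
static void convexGaps(const std::vector<double>& x, std::vector<double>& gaps) {
  int n = (int)x.size();
  gaps.assign(n, 0.0);
  std::vector<int> hull;
  auto lowY = [&](int i) { return (double)i / n; };
  auto upY  = [&](int i) { return (double)(i + 1) / n; };
  for (int m = 0; m < n; ++m) {
    while (hull.size() >= 2) {
      int a = hull[hull.size() - 2], b = hull[hull.size() - 1];
      double cross = (x[b] - x[a]) * (lowY(m) - lowY(a)) -
                     (x[m] - x[a]) * (lowY(b) - lowY(a));
      if (cross <= 0) hull.pop_back(); else break;
    }
    hull.push_back(m);
    double gap = 0.0;
    size_t seg = 0;
    for (int i = 0; i < m; ++i) {
      while (seg + 1 < hull.size() && x[hull[seg + 1]] <= x[i]) ++seg;
      double g;
      int a = hull[seg];
      if (seg + 1 >= hull.size() || x[hull[seg + 1]] == x[a]) {
        g = upY(i) - lowY(a);
      } else {
        int b = hull[seg + 1];
        double yi = lowY(a) + (lowY(b) - lowY(a)) * (x[i] - x[a]) / (x[b] - x[a]);
        g = upY(i) - yi;
      }
      if (g > gap) gap = g;
    }
    gaps[m] = gap;
  }
}

// [[Rcpp::export]]
double cpp_dip(NumericVector xs) {
  int n = xs.size();
  if (n < 2) return 0.0;
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  if (x[0] == x[n - 1]) return 0.0;

  std::vector<double> gapL;
  convexGaps(x, gapL);

  // right side via the mirror (x, y) -> (-x, 1 - y), which swaps the roles
  // of the upper/lower corners and turns the concave majorant into a
  // convex minorant of the reflected sample.
  std::vector<double> z(n);
  for (int i = 0; i < n; ++i) z[i] = -x[n - 1 - i];
  std::vector<double> gapZ;
  convexGaps(z, gapZ);

  double best = 1.0;
  for (int m = 0; m < n; ++m) {
    double d = std::max(gapL[m], gapZ[n - 1 - m]);
    if (d < best) best = d;
  }
  double dip = 0.5 * best;
  double lo = 0.5 / n;
  return dip < lo ? lo : dip;
}
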