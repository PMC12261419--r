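<svg xmlns="http://www.w3.org/2000/svg" width="460" height="400" viewBox="0 0 460 400">
  <style>
    text { font-family: sans-serif; font-size: 13px; }
    .node { font-weight: bold; font-size: 15px; }
    .edge { stroke: #555; stroke-width: 1.4; fill: none; marker-end: url(#arr); }
    .weight { fill: #b30000; font-weight: bold; }
    .weight.zero { fill: #bbbbbb; }
    .fname { fill: #333; font-size: 11px; }
  </style>
  <defs>
    <marker id="arr" markerWidth="8" markerHeight="8" refX="7" refY="3" orient="auto">
      <path d="M0,0 L7,3 L0,6 z" fill="#555"/>
    </marker>
  </defs>
  <text class="node" x="210" y="50">N2</text>
  <text class="node" x="60" y="330">NH3</text>
  <text class="node" x="360" y="330">NO3-</text>
  <path class="edge" d="M200,60 L85,315"/>
  <text class="fname" x="60" y="180">nitrogen fixation</text>
  <text class="{{nitrogen_fixation_w.class}}" x="80" y="200">{{nitrogen_fixation_w.label}}</text>
  <path class="edge" d="M110,335 L345,335"/>
  <text class="fname" x="180" y="320">nitrification</text>
  <text class="{{nitrification_w.class}}" x="200" y="355">{{nitrification_w.label}}</text>
  <path class="edge" d="M370,315 L235,60"/>
  <text class="fname" x="320" y="180">denitrification</text>
  <text class="{{denitrification_w.class}}" x="330" y="200">{{denitrification_w.label}}</text>
</svg>
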