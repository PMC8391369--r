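<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
<topic name="visited_places" description="places that were meaningful in the patient's life">
  <category trigger="true" entry="true">
    <pattern>lugares</pattern>
    <template><random><li>¿Es verdad que conociste <get name="lugar_visitado"/>?</li><li>¿Te gustaría platicar de tu viaje a <get name="lugar_visitado"/>?</li><li>¿Qué lugar bonito recuerdas haber visitado?</li></random></template>
  </category>
  <category trigger="true">
    <pattern>lugares *</pattern>
    <template><srai>lugares</srai></template>
  </category>
  <category trigger="true">
    <pattern>* lugares</pattern>
    <template><srai>lugares</srai></template>
  </category>
  <category trigger="true">
    <pattern>* lugares *</pattern>
    <template><srai>lugares</srai></template>
  </category>
  <category>
    <pattern>sí</pattern>
    <template><random><li>¡Qué bien! ¿Qué fue lo que más te gustó de <get name="lugar_visitado"/>?</li><li>¡Muy bien! ¿Me cuentas más de eso?</li></random></template>
  </category>
  <category>
    <pattern>sí *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* sí</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>si *</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>* si</pattern>
    <template><srai>sí</srai></template>
  </category>
  <category>
    <pattern>no</pattern>
    <template><random><li>Está bien. ¿De qué otra cosa te gustaría platicar?</li><li>No hay problema. ¿Hay otro tema que te guste más?</li></random></template>
  </category>
  <category>
    <pattern>no *</pattern>
    <template><srai>no</srai></template>
  </category>
  <category fallback="true">
    <pattern>fallback</pattern>
    <template><random><li>Entiendo. ¿Me cuentas un poco más?</li><li>Ya veo. ¿Qué más recuerdas de eso?</li></random></template>
  </category>
</topic>
</aiml>
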