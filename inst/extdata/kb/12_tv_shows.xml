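<?xml version="1.0" encoding="UTF-8"?>
<aiml version="subset-1" language="es">
<topic name="tv_shows" description="favorite television programs">
  <category trigger="true" entry="true">
    <pattern>televisión</pattern>
    <template><random><li>¿Es verdad que te gusta ver <get name="programa_tv"/>?</li><li>¿Te gustaría platicar de <get name="programa_tv"/>?</li><li>¿Qué programa de televisión te gusta más?</li></random></template>
  </category>
  <category trigger="true">
    <pattern>televisión *</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category trigger="true">
    <pattern>* televisión</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category trigger="true">
    <pattern>* televisión *</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category trigger="true">
    <pattern>television</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category trigger="true">
    <pattern>television *</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category trigger="true">
    <pattern>* television</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category trigger="true">
    <pattern>* television *</pattern>
    <template><srai>televisión</srai></template>
  </category>
  <category>
    <pattern>sí</pattern>
    <template><random><li>¡Qué bien! ¿Qué es lo que más te gusta de <get name="programa_tv"/>?</li><li>¡Muy bien! ¿Me cuentas más de eso?</li></random></template>
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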